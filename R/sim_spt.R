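#' Configuration for the single-particle tracking movie simulator
#'
#' Defaults emulate a TIRF single-molecule acquisition: 10 Hz for 500
#' frames, 0.16 um pixels, receptor surface density below 4.5 particles/um2,
#' a mix of oligomeric states, and a monomer fluorophore brightness of
#' 69.33 +/- 3.26 a.u. Particle motion is Brownian with reflective
#' boundaries; photobleaching is per-fluorophore exponential survival.
#'
#' @param field_px field edge length in pixels (square field).
#' @param pixel_size pixel size, micrometres.
#' @param n_frames number of frames.
#' @param frame_interval frame interval, seconds.
#' @param psf_sigma PSF standard deviation, micrometres.
#' @param density particle surface density, particles/um2. Must not exceed
#'   4.5 (the sparse single-molecule regime the tracker assumes).
#' @param oligomer_probs probability of a particle containing n = 1, 2, ...
#'   receptors; must sum to 1.
#' @param monomer_mean,monomer_sd per-fluorophore brightness distribution
#'   (integrated spot intensity of one fluorophore, a.u.).
#' @param mobile_frac fraction of particles that diffuse; the rest are
#'   immobile (D = 0).
#' @param d_mobile diffusion coefficient of mobile particles, um2/s.
#' @param read_noise_sd Gaussian camera read noise sd per pixel, a.u.
#' @param shot_noise logical; apply Poisson shot noise to the expected
#'   image (1 a.u. treated as 1 photoelectron).
#' @param camera_baseline electronic offset added after photon statistics
#'   (a.u.); keeps the background away from the zero clip, as real
#'   cameras do.
#' @param bleach_rate per-fluorophore photobleaching rate, 1/s.
#' @param seed integer seed; every simulation from the same config is
#'   bit-reproducible.
#' @return A validated config list of class `spt_sim_config`.
#' @export
spt_sim_config <- function(field_px = 64, pixel_size = 0.16, n_frames = 500,
                           frame_interval = 0.1, psf_sigma = 0.16,
                           density = 0.5,
                           oligomer_probs = c(0.40, 0.25, 0.20, 0.15),
                           monomer_mean = 69.33, monomer_sd = 3.26,
                           mobile_frac = 0.82, d_mobile = 0.017,
                           read_noise_sd = 2, shot_noise = TRUE,
                           camera_baseline = 100, bleach_rate = 0.002,
                           seed = 1L) {
  cfg <- list(field_px = as.integer(field_px), pixel_size = pixel_size,
              n_frames = as.integer(n_frames), frame_interval = frame_interval,
              psf_sigma = psf_sigma, density = density,
              oligomer_probs = oligomer_probs, monomer_mean = monomer_mean,
              monomer_sd = monomer_sd, mobile_frac = mobile_frac,
              d_mobile = d_mobile, read_noise_sd = read_noise_sd,
              shot_noise = isTRUE(shot_noise),
              camera_baseline = camera_baseline,
              bleach_rate = bleach_rate, seed = as.integer(seed))
  if (cfg$density > 4.5)
    stop("density exceeds 4.5 particles/um2 (sparse tracking regime)")
  if (abs(sum(cfg$oligomer_probs) - 1) > 1e-8)
    stop("oligomer_probs must sum to 1")
  if (any(cfg$oligomer_probs < 0)) stop("oligomer_probs must be >= 0")
  if (cfg$d_mobile < 0 || cfg$bleach_rate < 0 || cfg$read_noise_sd < 0)
    stop("rates and noise levels must be >= 0")
  if (cfg$mobile_frac < 0 || cfg$mobile_frac > 1)
    stop("mobile_frac must be in [0, 1]")
  if (cfg$frame_interval <= 0 || cfg$pixel_size <= 0 || cfg$psf_sigma <= 0)
    stop("pixel_size, frame_interval and psf_sigma must be > 0")
  class(cfg) <- "spt_sim_config"
  cfg
}

#' Simulate a TIRF single-molecule movie with ground truth
#'
#' Renders diffusing and immobile fluorescent particles of mixed oligomeric
#' state into an image stack. Each fluorophore gets a fixed brightness drawn
#' from Normal(monomer_mean, monomer_sd) and survives photobleaching as an
#' independent exponential; a particle's emitted intensity at a frame is the
#' summed brightness of its surviving fluorophores, convolved with a
#' Gaussian PSF. Mobile particles take Brownian steps with per-axis sd
#' sqrt(2 D dt) and reflect at the field boundary.
#'
#' @param config an [spt_sim_config()].
#' @return A list with `stack` (an [image_stack()]) and `truth`, a data
#'   frame with one row per particle per frame: `frame` (0-based),
#'   `particle_id`, `x_px`, `y_px` (0-based pixel coordinates of the true
#'   centre), `oligomer_n`, `fluors_alive`, `intensity` (true emitted
#'   integrated intensity, a.u.), and logical `mobile`.
#' @export
simulate_spt_movie <- function(config = spt_sim_config()) {
  stopifnot(inherits(config, "spt_sim_config"))
  set.seed(config$seed)
  L_um <- config$field_px * config$pixel_size
  area <- L_um^2
  n_part <- round(config$density * area)
  if (n_part < 1) stop("empty field: density x area < 1 particle")
  TT <- config$n_frames
  dt <- config$frame_interval

  olig <- sample.int(length(config$oligomer_probs), n_part, replace = TRUE,
                     prob = config$oligomer_probs)
  mobile <- runif(n_part) < config$mobile_frac
  sd_step <- sqrt(2 * config$d_mobile * dt) / config$pixel_size  # px

  # positions in 0-based px, reflective boundaries on [0, field_px - 1]
  lim <- config$field_px - 1
  x <- matrix(0, TT, n_part)
  y <- matrix(0, TT, n_part)
  x[1, ] <- runif(n_part, 0, lim)
  y[1, ] <- runif(n_part, 0, lim)
  if (TT > 1) {
    for (t in 2:TT) {
      dxy <- matrix(0, n_part, 2)
      if (any(mobile) && sd_step > 0)
        dxy[mobile, ] <- rnorm(2 * sum(mobile), 0, sd_step)
      x[t, ] <- reflect(x[t - 1, ] + dxy[, 1], lim)
      y[t, ] <- reflect(y[t - 1, ] + dxy[, 2], lim)
    }
  }

  # per-fluorophore brightness and bleaching
  p_surv <- exp(-config$bleach_rate * dt)
  alive <- matrix(0L, TT, n_part)
  inten <- matrix(0, TT, n_part)
  for (k in seq_len(n_part)) {
    b <- rnorm(olig[k], config$monomer_mean, config$monomer_sd)
    state <- rep(TRUE, olig[k])
    for (t in seq_len(TT)) {
      alive[t, k] <- sum(state)
      inten[t, k] <- sum(b[state])
      if (p_surv < 1) state <- state & (runif(olig[k]) < p_surv)
    }
  }

  spots <- cbind(frame = rep(seq_len(TT) - 1L, n_part),
                 x = as.vector(x), y = as.vector(y),
                 amp = as.vector(inten))
  frames <- render_stack(spots, config$psf_sigma / config$pixel_size,
                         config$field_px, config$field_px, TT)
  if (config$shot_noise) {
    v <- rpois(length(frames), lambda = as.vector(frames))
    frames <- array(as.numeric(v), dim(frames))
  }
  frames <- frames + config$camera_baseline
  if (config$read_noise_sd > 0)
    frames <- frames + rnorm(length(frames), 0, config$read_noise_sd)
  frames[frames < 0] <- 0

  truth <- data.frame(
    frame = rep(seq_len(TT) - 1L, n_part),
    particle_id = rep(seq_len(n_part), each = TT),
    x_px = as.vector(x), y_px = as.vector(y),
    oligomer_n = rep(olig, each = TT),
    fluors_alive = as.vector(alive),
    intensity = as.vector(inten),
    mobile = rep(mobile, each = TT))
  truth <- truth[order(truth$frame, truth$particle_id), ]
  rownames(truth) <- NULL

  list(stack = image_stack(frames, pixel_size = config$pixel_size,
                           frame_interval = dt),
       truth = truth, config = config)
}

reflect <- function(p, lim) {
  # reflect positions into [0, lim]
  p <- abs(p)
  over <- p > lim
  p[over] <- 2 * lim - p[over]
  # a very large step could still overshoot; clamp by repeating once
  p[p < 0] <- abs(p[p < 0])
  p[p > lim] <- lim
  p
}

#' Simulate localized Brownian trajectories directly
#'
#' Bypasses image formation: trajectory coordinates are the true Brownian
#' path plus independent Gaussian localization error per frame. This is the
#' generator used to validate the MSD / D1-4 estimators and to calibrate
#' the immobile-classification threshold at matched noise.
#'
#' @param n number of trajectories.
#' @param len trajectory length in frames; a scalar, or a length-2 range
#'   from which lengths are drawn uniformly.
#' @param d diffusion coefficient of mobile trajectories, um2/s.
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres (output coordinates are px).
#' @param sigma_loc localization error sd, micrometres (default 0.02).
#' @param mobile_frac fraction of trajectories with diffusion `d`; the rest
#'   are immobile (true D = 0, still subject to localization error).
#' @param intensity optional constant intensity to attach to detections.
#' @return A `trajectories` data frame (traj_id, frame, x, y, intensity)
#'   with attributes `pixel_size`, `frame_interval` and `truth_mobile`
#'   (logical per trajectory).
#' @export
simulate_trajectories <- function(n, len = c(50, 500), d = 0.017, dt = 0.1,
                                  pixel_size = 0.16, sigma_loc = 0.02,
                                  mobile_frac = 1, intensity = NA_real_) {
  lens <- if (length(len) == 2) sample(len[1]:len[2], n, replace = TRUE)
          else rep(as.integer(len), n)
  mob <- runif(n) < mobile_frac
  sd_step <- sqrt(2 * d * dt) / pixel_size
  sd_loc <- sigma_loc / pixel_size
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- lens[i]
    if (mob[i] && sd_step > 0) {
      xs <- cumsum(c(0, rnorm(m - 1, 0, sd_step)))
      ys <- cumsum(c(0, rnorm(m - 1, 0, sd_step)))
    } else {
      xs <- ys <- rep(0, m)
    }
    out[[i]] <- data.frame(traj_id = i, frame = seq_len(m) - 1L,
                           x = xs + rnorm(m, 0, sd_loc),
                           y = ys + rnorm(m, 0, sd_loc),
                           intensity = intensity)
  }
  res <- do.call(rbind, out)
  attr(res, "pixel_size") <- pixel_size
  attr(res, "frame_interval") <- dt
  attr(res, "truth_mobile") <- mob
  class(res) <- c("trajectories", "data.frame")
  res
}

#' Simulate a photobleaching intensity trace
#'
#' Constant summed brightness of surviving fluorophores plus Gaussian
#' measurement noise; used to validate bleaching-step counting.
#'
#' @param n_fluor initial fluorophore count.
#' @param n_frames trace length.
#' @param dt frame interval, seconds.
#' @param bleach_rate per-fluorophore bleaching rate, 1/s.
#' @param monomer_mean,monomer_sd per-fluorophore brightness distribution.
#' @param noise_sd measurement noise sd per frame, a.u.
#' @return A list: `trace` (numeric), `alive` (integer per frame),
#'   `n_steps_true` (number of distinct downward steps).
#' @export
simulate_bleach_trace <- function(n_fluor, n_frames = 100, dt = 0.1,
                                  bleach_rate = 0.1, monomer_mean = 69.33,
                                  monomer_sd = 3.26, noise_sd = 5) {
  b <- rnorm(n_fluor, monomer_mean, monomer_sd)
  death <- rexp(n_fluor, bleach_rate)
  tvec <- (seq_len(n_frames) - 1) * dt
  alive_mat <- outer(tvec, death, `<`)
  trace <- as.vector(alive_mat %*% b) + rnorm(n_frames, 0, noise_sd)
  alive <- rowSums(alive_mat)
  list(trace = trace, alive = as.integer(alive),
       n_steps_true = length(unique(death[death < max(tvec)])))
}
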
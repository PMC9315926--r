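#' Time-averaged mean squared displacement of one trajectory
#'
#' MSD(n dt) is the average over all start points of the squared
#' displacement at lag n, using overlapping windows. Only displacement
#' pairs whose frame difference is exactly n contribute, so trajectories
#' with gaps are handled without inflating the MSD.
#'
#' @param traj data frame with columns `frame`, `x`, `y` (pixels) for a
#'   single trajectory.
#' @param pixel_size pixel size, micrometres.
#' @param frame_interval frame interval, seconds.
#' @param max_lag largest lag in frames.
#' @return An `msd_curve` data frame: `lag_s` (seconds), `msd` (um2),
#'   `n_pairs`.
#' @export
compute_msd <- function(traj, pixel_size, frame_interval, max_lag = 4) {
  stopifnot(all(c("frame", "x", "y") %in% names(traj)))
  if (nrow(traj) < 5) stop("too short for D1-4 (need >= 5 localizations)")
  if (nrow(traj) < max_lag + 1)
    stop("trajectory length must be >= max_lag + 1")
  traj <- traj[order(traj$frame), ]
  f <- traj$frame
  x <- traj$x * pixel_size
  y <- traj$y * pixel_size
  lag_s <- seq_len(max_lag) * frame_interval
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  n <- nrow(traj)
  for (lg in seq_len(max_lag)) {
    # pairs (i, j) with frame difference exactly lg
    j <- match(f + lg, f)
    ok <- !is.na(j)
    npairs[lg] <- sum(ok)
    msd[lg] <- if (any(ok))
      mean((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2) else NA_real_
  }
  res <- data.frame(lag_s = lag_s, msd = msd, n_pairs = npairs)
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Short time-lag diffusion coefficient D1-4
#'
#' Unweighted least-squares line through the first four MSD points
#' (lags 1-4). For 2D lateral diffusion MSD = 4 D t + 4 sigma_loc^2, so
#' D1-4 is slope/4 and the intercept estimates four times the squared
#' localization error. Negative slopes are returned as-is; classification
#' downstream decides what to do with them.
#'
#' @param msd an `msd_curve` with at least 4 finite lags.
#' @return List with `d14` (um2/s), `intercept` (um2), `slope`.
#' @export
fit_d14 <- function(msd) {
  m <- msd[seq_len(min(4, nrow(msd))), ]
  m <- m[is.finite(m$msd), ]
  if (nrow(m) < 4) stop("need MSD at lags 1-4 to fit D1-4")
  fit <- lm(msd ~ lag_s, data = m)
  slope <- unname(coef(fit)[2])
  list(d14 = slope / 4, intercept = unname(coef(fit)[1]), slope = slope)
}

#' Classify a trajectory as mobile or immobile
#'
#' A trajectory is immobile when its D1-4 does not exceed the threshold.
#' The threshold should come from [calibrate_immobile_threshold()] so it
#' reflects the apparent diffusion produced by pure localization noise.
#'
#' @param d14 numeric vector of D1-4 values, um2/s.
#' @param threshold immobility cutoff, um2/s (> 0).
#' @return Character vector, `"mobile"` or `"immobile"`.
#' @export
classify_mobility <- function(d14, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  ifelse(d14 <= threshold, "immobile", "mobile")
}

#' Calibrate the immobility threshold from an immobile-only simulation
#'
#' Simulates trajectories with true D = 0 at the given localization noise
#' and returns the 95th percentile of their apparent D1-4, so that at most
#' 5% of truly immobile particles are miscalled mobile by construction.
#'
#' @param n number of simulated immobile trajectories.
#' @param len trajectory length in frames (scalar or range, as in
#'   [simulate_trajectories()]).
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @param sigma_loc localization error sd, micrometres.
#' @param probs quantile of the null D1-4 distribution used as threshold.
#' @return Threshold in um2/s.
#' @export
calibrate_immobile_threshold <- function(n = 2000, len = c(50, 500),
                                         dt = 0.1, pixel_size = 0.16,
                                         sigma_loc = 0.02, probs = 0.95) {
  tr <- simulate_trajectories(n, len = len, d = 0, dt = dt,
                              pixel_size = pixel_size,
                              sigma_loc = sigma_loc, mobile_frac = 0)
  d <- analyze_dynamics(tr, threshold = Inf)$d14
  unname(quantile(d, probs))
}

#' Per-trajectory dynamics: D1-4, intercept, mobility class
#'
#' @param trajs a `trajectories` data frame (or any data frame with
#'   traj_id, frame, x, y).
#' @param pixel_size,frame_interval calibration; defaults come from the
#'   `trajectories` attributes.
#' @param threshold immobility cutoff, um2/s; `Inf` labels everything
#'   mobile (useful for calibration).
#' @return A `dynamics_result` data frame: `traj_id`, `n_frames`, `d14`,
#'   `intercept`, `class`.
#' @export
analyze_dynamics <- function(trajs, pixel_size = attr(trajs, "pixel_size"),
                             frame_interval = attr(trajs, "frame_interval"),
                             threshold = NULL) {
  stopifnot(!is.null(pixel_size), !is.null(frame_interval))
  if (is.null(threshold))
    threshold <- calibrate_immobile_threshold(dt = frame_interval,
                                              pixel_size = pixel_size)
  rows <- lapply(split(trajs[c("traj_id", "frame", "x", "y")],
                       trajs$traj_id), function(tr) {
    id <- tr$traj_id[1]
    if (nrow(tr) < 5) return(NULL)
    fit <- tryCatch(
      fit_d14(compute_msd(tr, pixel_size, frame_interval, max_lag = 4)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(traj_id = id, n_frames = nrow(tr), d14 = fit$d14,
               intercept = fit$intercept)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(traj_id = integer(0), n_frames = integer(0),
                      d14 = numeric(0), intercept = numeric(0))
  res$class <- if (nrow(res)) classify_mobility(res$d14, threshold)
               else character(0)
  attr(res, "threshold") <- threshold
  class(res) <- c("dynamics_result", "data.frame")
  res
}

#' Population summary of trajectory dynamics
#'
#' Reports the percentage of mobile and immobile trajectories and the
#' median D1-4 of the mobile subset only (the immobile population would
#' otherwise drag the median toward the localization-noise floor).
#'
#' @param dynamics a `dynamics_result` from [analyze_dynamics()].
#' @param label group label.
#' @return A `population_summary` list: `label`, `n`, `pct_mobile`,
#'   `pct_immobile`, `median_d14_mobile`, `d14_mobile` (the per-trajectory
#'   values, kept for group testing).
#' @export
population_summary <- function(dynamics, label = "group") {
  n <- nrow(dynamics)
  if (n == 0) stop("empty group")
  n_mob <- sum(dynamics$class == "mobile")
  d_mob <- dynamics$d14[dynamics$class == "mobile"]
  structure(list(label = label, n = n, n_mobile = n_mob,
                 pct_mobile = 100 * n_mob / n,
                 pct_immobile = 100 * (n - n_mob) / n,
                 median_d14_mobile = median(d_mob),
                 d14_mobile = d_mob),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s: n = %d\n", x$label, x$n))
  cat(sprintf("  mobile %.1f%% / immobile %.1f%%\n",
              x$pct_mobile, x$pct_immobile))
  cat(sprintf("  median D1-4 (mobile) = %.4g um2/s\n",
              x$median_d14_mobile))
  invisible(x)
}

#' Compare two trajectory populations
#'
#' Mobile D1-4 distributions are compared with a two-tailed Mann-Whitney
#' (Wilcoxon rank-sum) test; mobile/immobile counts with a two-tailed
#' chi-square test on the 2x2 contingency table (no continuity
#' correction).
#'
#' @param a,b `population_summary` objects.
#' @return A `population_comparison` list with the Mann-Whitney statistic
#'   and p-value, the chi-square statistic, df and p-value, and the
#'   contingency table.
#' @export
compare_populations <- function(a, b) {
  stopifnot(inherits(a, "population_summary"),
            inherits(b, "population_summary"))
  if (a$n < 2 || b$n < 2) stop("empty group: need n >= 2 per group")
  mw <- wilcox.test(a$d14_mobile, b$d14_mobile, alternative = "two.sided",
                    exact = FALSE, correct = FALSE)
  tab <- rbind(c(a$n_mobile, a$n - a$n_mobile),
               c(b$n_mobile, b$n - b$n_mobile))
  dimnames(tab) <- list(c(a$label, b$label), c("mobile", "immobile"))
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(mw_u = unname(mw$statistic), mw_p = mw$p.value,
                 chisq = unname(cs$statistic), chisq_df = unname(cs$parameter),
                 chisq_p = cs$p.value, table = tab,
                 labels = c(a$label, b$label)),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("<population_comparison> %s vs %s\n",
              x$labels[1], x$labels[2]))
  cat(sprintf("  Mann-Whitney U = %.4g, p = %.4g (mobile D1-4)\n",
              x$mw_u, x$mw_p))
  cat(sprintf("  chi-square = %.4g (df %d), p = %.4g (mobility counts)\n",
              x$chisq, x$chisq_df, x$chisq_p))
  invisible(x)
}
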
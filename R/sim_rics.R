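#' Configuration for the raster-scan (RICS) simulator
#'
#' Defaults match a confocal membrane acquisition: 256 x 256 px, 80.4 nm
#' pixels, 4 us dwell, 200 consecutive frames, and a 2D Gaussian beam
#' exp(-2 r^2 / w0^2). "Mean particles per beam area" uses beam area
#' pi * w0^2, the effective area for which the fluctuation amplitude is
#' G(0) = 1/N.
#'
#' @param image_px image edge length, pixels.
#' @param pixel_size pixel size, micrometres.
#' @param dwell_time pixel dwell time, seconds.
#' @param line_time time between line starts, seconds; defaults to
#'   image_px * dwell_time (no flyback). Must be >= image width x dwell.
#' @param n_frames number of raster frames.
#' @param d diffusion coefficient, um2/s.
#' @param n_per_beam mean number of particles per beam area (pi * w0^2).
#' @param w0 1/e^2 beam waist, micrometres.
#' @param brightness expected counts per particle per dwell at beam centre.
#' @param static_amp brightness of immobile background structures (0 = none);
#'   used to exercise moving-average detrending.
#' @param n_static number of immobile structures when `static_amp > 0`.
#' @param shot_noise logical; apply Poisson photon noise.
#' @param per_pixel advance particle positions every pixel instead of every
#'   line. The per-line default is accurate when D x line_time corresponds
#'   to motion far below a pixel, which holds for membrane-like D.
#' @param seed integer seed.
#' @return A validated config list of class `rics_sim_config`.
#' @export
rics_sim_config <- function(image_px = 256, pixel_size = 0.0804,
                            dwell_time = 4e-6, line_time = NULL,
                            n_frames = 200, d = 0.5, n_per_beam = 5,
                            w0 = 0.25, brightness = 2, static_amp = 0,
                            n_static = 20, shot_noise = TRUE,
                            per_pixel = FALSE, seed = 1L) {
  if (is.null(line_time)) line_time <- image_px * dwell_time
  cfg <- list(image_px = as.integer(image_px), pixel_size = pixel_size,
              dwell_time = dwell_time, line_time = line_time,
              n_frames = as.integer(n_frames), d = d,
              n_per_beam = n_per_beam, w0 = w0, brightness = brightness,
              static_amp = static_amp, n_static = as.integer(n_static),
              shot_noise = isTRUE(shot_noise), per_pixel = isTRUE(per_pixel),
              seed = as.integer(seed))
  if (cfg$d < 0) stop("d must be >= 0")
  if (cfg$line_time < cfg$image_px * cfg$dwell_time - 1e-12)
    stop("line_time must be >= image width x dwell_time")
  if (cfg$w0 < cfg$pixel_size)
    warning("undersampled PSF: w0 < pixel size")
  class(cfg) <- "rics_sim_config"
  cfg
}

#' Simulate a raster-scanned image series of diffusing particles
#'
#' Each pixel samples the particle field at its own acquisition time
#' (frame offset + line index x line time + column index x dwell), which is
#' what gives RICS its hidden temporal structure. Particles take Brownian
#' steps between scan lines (or between pixels with `per_pixel = TRUE`)
#' under periodic boundary conditions, preserving stationarity for
#' correlation analysis.
#'
#' @param config an [rics_sim_config()].
#' @return An [image_stack()] with raster timing metadata.
#' @export
simulate_rics_series <- function(config = rics_sim_config()) {
  stopifnot(inherits(config, "rics_sim_config"))
  set.seed(config$seed)
  L <- config$image_px * config$pixel_size
  beam_area <- pi * config$w0^2
  n_part <- round(config$n_per_beam / beam_area * L^2)
  xy <- matrix(runif(2 * n_part, 0, L), ncol = 2)
  frames <- raster_scan(xy, config$image_px, config$image_px,
                        config$n_frames, config$pixel_size,
                        config$dwell_time, config$line_time, config$d,
                        config$w0, config$brightness, config$per_pixel)
  if (config$static_amp > 0) {
    sxy <- matrix(runif(2 * config$n_static, 0, L), ncol = 2)
    static <- raster_scan(sxy, config$image_px, config$image_px, 1L,
                          config$pixel_size, config$dwell_time,
                          config$line_time, 0, config$w0,
                          config$static_amp, FALSE)
    frames <- frames + as.vector(static[, , 1])
  }
  if (config$shot_noise) {
    v <- rpois(length(frames), lambda = as.vector(frames))
    frames <- array(as.numeric(v), dim(frames))
  }
  image_stack(frames, pixel_size = config$pixel_size,
              frame_interval = config$image_px * config$line_time,
              dwell_time = config$dwell_time, line_time = config$line_time)
}
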
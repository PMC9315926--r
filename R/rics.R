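#' Raster acquisition parameters for RICS
#'
#' @param pixel_size pixel size delta_r, micrometres.
#' @param dwell_time pixel dwell tau_p, seconds.
#' @param line_time line period tau_l, seconds; defaults to
#'   roi_size x dwell (no flyback) and is reported with every fit because
#'   it is rarely stored in image files.
#' @param w0 1/e^2 PSF beam waist, micrometres. The default 0.25 um is
#'   typical for 488 nm excitation through a high-NA water objective.
#' @param roi_size analysis ROI edge, pixels (power of 2).
#' @param window moving-average detrending window, frames.
#' @return A `raster_params` list.
#' @export
raster_params <- function(pixel_size = 0.0804, dwell_time = 4e-6,
                          line_time = NULL, w0 = 0.25, roi_size = 64,
                          window = 10) {
  if (is.null(line_time)) line_time <- roi_size * dwell_time
  p <- list(pixel_size = pixel_size, dwell_time = dwell_time,
            line_time = line_time, w0 = w0, roi_size = as.integer(roi_size),
            window = as.integer(window))
  if (p$w0 <= 0) stop("w0 must be > 0")
  if (p$window < 2) stop("window must be >= 2")
  if (bitwAnd(p$roi_size, p$roi_size - 1L) != 0L)
    stop("roi_size must be a power of 2")
  if (p$line_time < p$roi_size * p$dwell_time - 1e-12)
    stop("line_time must be >= ROI width x dwell_time")
  class(p) <- "raster_params"
  p
}

#' Moving-average (background) subtraction
#'
#' Removes immobile and slow-moving structure before correlation
#' analysis: each frame has the centred moving average of `window`
#' neighbouring frames subtracted, and the global mean added back so the
#' mean intensity used for ACF normalization is preserved. Edge frames
#' use truncated windows.
#'
#' @param stack an [image_stack()].
#' @param window moving-average window, frames (< number of frames).
#' @return A detrended `image_stack`.
#' @export
moving_average_subtract <- function(stack, window = 10) {
  stopifnot(inherits(stack, "image_stack"))
  TT <- n_frames(stack)
  if (window >= TT) stop("window must be smaller than the number of frames")
  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1] * d[2], d[3])  # pixels x time
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  # banded averaging matrix: frame t gets mean of frames [t-lo, t+hi]
  W <- matrix(0, TT, TT)
  for (t in seq_len(TT)) {
    a <- max(1, t - half_lo); b <- min(TT, t + half_hi)
    W[a:b, t] <- 1 / (b - a + 1)
  }
  ma <- m %*% W
  out <- m - ma + mean(m)
  stk <- stack
  stk$frames <- array(out, d)
  stk
}

#' Raster-aware 2D spatial autocorrelation map
#'
#' Per frame, G(xi, psi) = <dI(x, y) dI(x + xi, y + psi)> / <I>^2 where
#' dI = I - <I> within the ROI; xi runs along the fast scan axis
#' (columns) and psi across lines (rows). Computed via zero-padded FFT so
#' no periodic wrap-around enters, with each lag normalized by its number
#' of overlapping pixel pairs, then averaged over frames. The zero-lag
#' value carries the shot-noise spike and is flagged for exclusion from
#' fitting.
#'
#' @param stack a detrended [image_stack()].
#' @param roi integer vector `c(row0, col0)` giving the 1-based upper-left
#'   corner of the ROI, or `NULL` to use the full frame (dimensions must
#'   then be the ROI size).
#' @param params a [raster_params()].
#' @param max_lag largest spatial lag retained in each direction.
#' @return An `acf_map` list: `G` (matrix over lags -max_lag..max_lag,
#'   rows = psi, cols = xi, dimnames carry the lags), `n_frames`,
#'   `mean_intensity`, `params`.
#' @export
compute_acf <- function(stack, roi = NULL, params = raster_params(),
                        max_lag = 16) {
  stopifnot(inherits(stack, "image_stack"))
  TT <- n_frames(stack)
  if (TT < 10) stop("need >= 10 frames for a stable ACF")
  n <- params$roi_size
  d <- dim(stack$frames)
  if (is.null(roi)) {
    if (d[1] < n || d[2] < n) stop("frame smaller than ROI")
    roi <- c(1L, 1L)
  }
  r0 <- roi[1]; c0 <- roi[2]
  if (r0 + n - 1 > d[1] || c0 + n - 1 > d[2]) stop("ROI outside image")
  if (max_lag >= n) stop("max_lag must be < ROI size")

  P <- 2L * n
  # overlap counts per circular lag of the zero-padded field
  ones <- matrix(0, P, P); ones[1:n, 1:n] <- 1
  Fo <- fft(ones)
  counts <- Re(fft(Fo * Conj(Fo), inverse = TRUE)) / (P * P)
  acc <- matrix(0, P, P)
  mean_i <- 0
  for (t in seq_len(TT)) {
    img <- stack$frames[r0:(r0 + n - 1), c0:(c0 + n - 1), t]
    mu <- mean(img)
    if (mu == 0) stop("zero mean intensity in ROI")
    pad <- matrix(0, P, P)
    pad[1:n, 1:n] <- img - mu
    Fp <- fft(pad)
    corr <- Re(fft(Fp * Conj(Fp), inverse = TRUE)) / (P * P)
    acc <- acc + corr / (counts + (counts == 0)) / mu^2
    mean_i <- mean_i + mu
  }
  acc <- acc / TT
  mean_i <- mean_i / TT
  # reorder circular lags to -max_lag..max_lag
  idx <- function(l) ifelse(l >= 0, l + 1L, P + l + 1L)
  lags <- -max_lag:max_lag
  G <- acc[idx(lags), idx(lags), drop = FALSE]
  dimnames(G) <- list(psi = lags, xi = lags)
  structure(list(G = G, lags = lags, n_frames = TT,
                 mean_intensity = mean_i, params = params),
            class = "acf_map")
}

#' @export
print.acf_map <- function(x, ...) {
  cat(sprintf("<acf_map> lags -%d..%d, %d frames averaged, G(0,0) = %.4g\n",
              max(x$lags), max(x$lags), x$n_frames,
              x$G[x$lags == 0, x$lags == 0]))
  invisible(x)
}

#' RICS diffusion model for 2D membrane diffusion
#'
#' G(xi, psi) = offset + G0 (1 + 4 D tau / w0^2)^-1
#'   exp(-(delta_r^2 (xi^2 + psi^2) / w0^2) / (1 + 4 D tau / w0^2)),
#' with tau(xi, psi) = tau_p |xi| + tau_l |psi|: each spatial lag is also
#' a time lag set by the raster scan. No axial term (membrane form).
#'
#' @param xi,psi pixel lag along the fast axis and line lag (vectors of
#'   equal length or broadcastable).
#' @param d diffusion coefficient, um2/s.
#' @param g0 amplitude (approximately 1/N per beam area).
#' @param offset baseline.
#' @param params a [raster_params()].
#' @return G values.
#' @export
rics_model <- function(xi, psi, d, g0, offset, params) {
  if (params$w0 <= 0) stop("w0 must be > 0")
  offset + rics_kernel(xi, psi, 0, d, g0, params)
}

# space-time correlation kernel at spatial lag (xi, psi) pixels and an
# extra time lag on top of the scan-imposed tau(xi, psi)
rics_kernel <- function(xi, psi, extra_tau, d, g0, params) {
  tau <- params$dwell_time * abs(xi) + params$line_time * abs(psi) +
    extra_tau
  denom <- 1 + 4 * d * tau / params$w0^2
  g0 / denom *
    exp(-(params$pixel_size^2 * (xi^2 + psi^2) / params$w0^2) / denom)
}

# expected same-frame ACF after centred moving-average subtraction over
# `window` frames of period `frame_time`: the subtracted average is
# correlated with the frame through inter-frame diffusion, so
# G_det = G(tau) - (2/W) sum_j G(tau + |j| T) + (1/W^2) sum_jk G(tau + |k - j| T)
rics_model_detrended <- function(xi, psi, d, g0, offset, params,
                                 window, frame_time) {
  half_lo <- floor((window - 1) / 2)
  offs <- seq(-half_lo, window - 1 - half_lo)
  g <- rics_kernel(xi, psi, 0, d, g0, params)
  for (j in offs)
    g <- g - (2 / window) * rics_kernel(xi, psi, abs(j) * frame_time,
                                        d, g0, params)
  dd <- abs(outer(offs, offs, `-`))
  for (u in unique(as.vector(dd)))
    g <- g + (sum(dd == u) / window^2) *
      rics_kernel(xi, psi, u * frame_time, d, g0, params)
  offset + g
}

#' Fit the RICS model to an autocorrelation map
#'
#' Nonlinear least squares over lags within `fit_radius`, excluding the
#' shot-noise-contaminated zero lag. Initial amplitude comes from the
#' smallest nonzero lags; initial D is 0.5 um2/s. Confidence intervals
#' are Wald intervals from the Jacobian. Non-convergence is flagged in
#' the result, not raised.
#'
#' @param acf an `acf_map` from [compute_acf()].
#' @param params a [raster_params()]; defaults to the one stored in the
#'   map.
#' @param fit_radius largest |xi|, |psi| used in the fit.
#' @param detrend `NULL` when the map came from raw frames, or
#'   `list(window = , frame_time = )` when it came from a
#'   moving-average-subtracted stack: the fitted model then accounts for
#'   the correlation between a frame and its subtracted neighbours, which
#'   otherwise biases D downward at membrane-like diffusion.
#' @return A `rics_fit` list: `d`, `g0`, `offset`, their standard errors
#'   and 95% CIs, `r_squared`, `converged`, `residual_map`, `params`.
#' @export
fit_rics <- function(acf, params = acf$params, fit_radius = 16,
                     detrend = NULL) {
  stopifnot(inherits(acf, "acf_map"))
  lags <- acf$lags
  keep <- abs(lags) <= fit_radius
  xi <- rep(lags[keep], each = sum(keep))
  psi <- rep(lags[keep], times = sum(keep))
  g <- as.vector(acf$G[keep, keep])
  nz <- !(xi == 0 & psi == 0)
  df <- data.frame(xi = xi[nz], psi = psi[nz], g = g[nz])
  g0_init <- mean(df$g[abs(df$xi) + abs(df$psi) == 1])
  if (!is.finite(g0_init) || g0_init <= 0) g0_init <- max(df$g, 1e-6)
  model_fun <- if (is.null(detrend)) {
    function(xi, psi, d, g0, offset)
      rics_model(xi, psi, d, g0, offset, params)
  } else {
    function(xi, psi, d, g0, offset)
      rics_model_detrended(xi, psi, d, g0, offset, params,
                           detrend$window, detrend$frame_time)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ model_fun(xi, psi, d, g0, offset),
      data = df,
      start = list(d = 0.5, g0 = g0_init, offset = 0),
      lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(d = NA_real_, g0 = NA_real_, offset = NA_real_,
                          d_se = NA_real_, d_ci = c(NA, NA),
                          g0_se = NA_real_, g0_ci = c(NA, NA),
                          r_squared = NA_real_, converged = FALSE,
                          residual_map = NULL, params = params),
                     class = "rics_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  pred <- predict(fit)
  r2 <- 1 - sum((df$g - pred)^2) / sum((df$g - mean(df$g))^2)
  model_map <- outer(lags, lags, function(psi, xi)
    model_fun(xi, psi, cf["d"], cf["g0"], cf["offset"]))
  res_map <- acf$G - model_map
  converged <- isTRUE(fit$convInfo$isConv) &&
    is.finite(se[2]) && cf["g0"] > 1.96 * se[2]
  structure(list(d = unname(cf["d"]), g0 = unname(cf["g0"]),
                 offset = unname(cf["offset"]),
                 d_se = se[1], d_ci = unname(cf["d"]) + c(-1.96, 1.96) * se[1],
                 g0_se = se[2],
                 g0_ci = unname(cf["g0"]) + c(-1.96, 1.96) * se[2],
                 r_squared = r2, converged = converged,
                 residual_map = res_map, params = params),
            class = "rics_fit")
}

#' @export
print.rics_fit <- function(x, ...) {
  if (!isTRUE(x$converged))
    cat("<rics_fit> NOT CONVERGED (or amplitude indistinguishable from 0)\n")
  cat(sprintf("<rics_fit> D = %.4g um2/s [%.4g, %.4g], G0 = %.4g, R2 = %.3f\n",
              x$d, x$d_ci[1], x$d_ci[2], x$g0, x$r_squared))
  invisible(x)
}

#' Full RICS analysis of an image series
#'
#' Detrends the stack with a moving average, draws `n_rois` random ROIs
#' (mirroring the practice of sampling several cytoplasmic areas per
#' cell), fits each, and reports the per-ROI fits plus their mean D.
#' ROI placement uses the current RNG state, so set a seed for
#' reproducible sampling.
#'
#' @param stack an [image_stack()].
#' @param params a [raster_params()].
#' @param n_rois number of random ROIs.
#' @param max_lag,fit_radius ACF extent and fit region.
#' @return A `rics_result` list: `fits` (list of `rics_fit`), `d_mean`,
#'   `d_values`, `rois`.
#' @export
rics_analyze <- function(stack, params = raster_params(), n_rois = 4,
                         max_lag = 16, fit_radius = 16) {
  det <- moving_average_subtract(stack, params$window)
  d <- dim(stack$frames)
  n <- params$roi_size
  frame_time <- if (!is.na(stack$frame_interval)) stack$frame_interval
                else d[1] * params$line_time
  dt_info <- list(window = params$window, frame_time = frame_time)
  r0s <- sample.int(d[1] - n + 1, n_rois, replace = TRUE)
  c0s <- sample.int(d[2] - n + 1, n_rois, replace = TRUE)
  fits <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    acf <- compute_acf(det, roi = c(r0s[i], c0s[i]), params = params,
                       max_lag = max_lag)
    fits[[i]] <- fit_rics(acf, params, fit_radius, detrend = dt_info)
  }
  dv <- vapply(fits, function(f) f$d, 0)
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  structure(list(fits = fits, d_values = dv,
                 d_mean = mean(dv[ok]), n_converged = sum(ok),
                 rois = cbind(row = r0s, col = c0s), params = params),
            class = "rics_result")
}

#' @export
print.rics_result <- function(x, ...) {
  cat(sprintf("<rics_result> %d ROIs (%d converged), mean D = %.4g um2/s\n",
              length(x$fits), x$n_converged, x$d_mean))
  invisible(x)
}
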
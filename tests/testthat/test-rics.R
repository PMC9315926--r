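toy_params <- function(n = 16) raster_params(roi_size = n, window = 4)

test_that("FFT autocorrelation equals the brute-force oracle", {
  set.seed(71)
  arr <- array(runif(16 * 16 * 10, 1, 2), c(16, 16, 10))
  stk <- image_stack(arr, pixel_size = 0.08)
  am <- compute_acf(stk, roi = c(1, 1), params = toy_params(), max_lag = 5)
  for (xi in c(-4, -1, 0, 2, 5)) for (psi in c(-3, 0, 1, 4)) {
    oracle <- mean(vapply(1:10, function(t)
      acf_direct_oracle(arr[, , t], xi, psi), 0))
    expect_equal(am$G[as.character(psi), as.character(xi)], oracle,
                 tolerance = 1e-10)
  }
})

test_that("white noise decorrelates everywhere except zero lag", {
  set.seed(72)
  arr <- array(rpois(64 * 64 * 50, 100), c(64, 64, 50))
  stk <- image_stack(arr, pixel_size = 0.08)
  am <- compute_acf(stk, roi = c(1, 1),
                    params = raster_params(roi_size = 64), max_lag = 8)
  off <- am$G
  off[am$lags == 0, am$lags == 0] <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 5e-4)
  expect_gt(am$G["0", "0"], 5e-3)  # shot-noise spike
})

test_that("the model obeys its limiting forms", {
  p <- raster_params()
  # zero lag: amplitude plus offset
  expect_equal(rics_model(0, 0, 1, 0.2, 0.01, p), 0.21)
  # frozen limit: pure Gaussian PSF correlation
  xi <- -10:10
  frozen <- rics_model(xi, 0, 0, 0.2, 0, p)
  expect_equal(frozen, 0.2 * exp(-(p$pixel_size^2 * xi^2) / p$w0^2))
  # G is strictly decreasing in D at fixed lags near the beam centre
  # (at spatial lags beyond the waist, diffusive broadening can win)
  ds <- c(0.01, 0.1, 0.5, 1, 5, 20)
  for (lag in list(c(2, 0), c(0, 3), c(0, 1))) {
    g <- vapply(ds, function(d)
      rics_model(lag[1], lag[2], d, 0.2, 0, p), 0)
    expect_true(all(diff(g) < 0))
  }
  expect_error(raster_params(w0 = 0), "w0")
})

test_that("moving-average subtraction removes static structure", {
  img <- matrix(runif(32 * 32, 10, 20), 32, 32)
  arr <- array(rep(img, 40), c(32, 32, 40))
  stk <- image_stack(arr, pixel_size = 0.08)
  det <- moving_average_subtract(stk, 10)
  # all frames collapse to the global mean
  expect_lt(max(abs(det$frames - mean(arr))), 1e-9)
  expect_error(moving_average_subtract(stk, 40), "window")
})

test_that("a linear bleaching trend is flattened by detrending", {
  set.seed(73)
  base <- matrix(runif(32 * 32, 50, 60), 32, 32)
  arr <- array(0, c(32, 32, 60))
  for (t in 1:60) arr[, , t] <- base * (1 - 0.004 * t)
  stk <- image_stack(arr, pixel_size = 0.08)
  det <- moving_average_subtract(stk, 10)
  means <- apply(det$frames[, , 6:55], 3, mean)  # interior frames
  expect_lt(diff(range(means)) / mean(means), 0.01)
})

test_that("detrending is idempotent within tolerance", {
  set.seed(74)
  arr <- array(rnorm(32 * 32 * 40, 100, 5), c(32, 32, 40))
  stk <- image_stack(arr, pixel_size = 0.08)
  d1 <- moving_average_subtract(stk, 10)
  d2 <- moving_average_subtract(d1, 10)
  # interior frames: second pass changes little
  delta <- abs(d2$frames[, , 10:30] - d1$frames[, , 10:30])
  expect_lt(mean(delta) / mean(arr), 0.02)
})

test_that("a frozen field is reproduced identically without noise", {
  cfg <- rics_sim_config(image_px = 64, d = 0, n_frames = 5,
                         shot_noise = FALSE, seed = 75)
  stk <- simulate_rics_series(cfg)
  for (t in 2:5)
    expect_equal(stk$frames[, , t], stk$frames[, , 1], tolerance = 1e-12)
})

test_that("fast diffusion collapses the spatial correlation", {
  base <- list(image_px = 64, n_frames = 30, seed = 76,
               shot_noise = FALSE)
  p <- raster_params(roi_size = 64, line_time = 64 * 4e-6)
  width_at <- function(d) {
    cfg <- do.call(rics_sim_config, c(base, list(d = d)))
    am <- compute_acf(simulate_rics_series(cfg), roi = c(1, 1),
                      params = p, max_lag = 10)
    g <- am$G[, "0"]  # line-axis profile
    g0 <- max(g)
    sum(g > g0 / 4)  # crude width in lags
  }
  expect_lt(width_at(100), width_at(0))
})

test_that("ACF amplitude reflects particles per beam area", {
  cfg <- rics_sim_config(image_px = 128, d = 0.5, n_per_beam = 5,
                         n_frames = 60, shot_noise = FALSE, seed = 77)
  stk <- simulate_rics_series(cfg)
  p <- raster_params(roi_size = 128, line_time = cfg$line_time,
                     w0 = cfg$w0)
  am <- compute_acf(stk, roi = c(1, 1), params = p, max_lag = 4)
  # G at the smallest lags extrapolates the amplitude 1/N = 0.2
  g1 <- mean(c(am$G["0", "1"], am$G["0", "-1"],
               am$G["1", "0"], am$G["-1", "0"]))
  spatial_1 <- exp(-(p$pixel_size^2) / p$w0^2)
  expect_equal(g1 / spatial_1, 1 / 5, tolerance = 0.12)
})

test_that("an undersampled PSF warns at configuration time", {
  expect_warning(rics_sim_config(w0 = 0.05), "undersampled")
})

test_that("fitting pure noise is flagged rather than trusted", {
  set.seed(78)
  arr <- array(rpois(64 * 64 * 30, 50), c(64, 64, 30))
  stk <- image_stack(arr, pixel_size = 0.0804)
  p <- raster_params(roi_size = 64)
  am <- compute_acf(stk, roi = c(1, 1), params = p, max_lag = 16)
  f <- fit_rics(am, p)
  expect_false(isTRUE(f$converged) && f$g0_ci[1] > 0)
})
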
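make_traj <- function(x, y, frames = seq_along(x) - 1L)
  data.frame(traj_id = 1L, frame = frames, x = x, y = y)

test_that("MSD of a stationary trajectory is zero at all lags", {
  tr <- make_traj(rep(3, 20), rep(4, 20))
  m <- compute_msd(tr, pixel_size = 0.16, frame_interval = 0.1)
  expect_equal(m$msd, rep(0, 4))
  expect_equal(m$n_pairs, c(19L, 18L, 17L, 16L))
})

test_that("ballistic motion gives the quadratic closed form", {
  v <- 0.5  # um/s along x
  px <- 0.16; dt <- 0.1
  tr <- make_traj(v * dt * (0:19) / px, rep(0, 20))
  m <- compute_msd(tr, px, dt)
  expect_equal(m$msd, (v * m$lag_s)^2)
})

test_that("grand-mean Brownian MSD at one lag matches 4 D dt", {
  set.seed(31)
  tr <- simulate_trajectories(1000, len = 50, d = 0.017, dt = 0.1,
                              sigma_loc = 0)
  msd1 <- vapply(split(tr, tr$traj_id), function(p) {
    compute_msd(p, 0.16, 0.1)$msd[1]
  }, 0)
  expect_equal(mean(msd1), 4 * 0.017 * 0.1, tolerance = 0.05)
})

test_that("D1-4 line fit is exact on exact data", {
  m <- data.frame(lag_s = (1:4) * 0.1,
                  msd = c(0.004, 0.008, 0.012, 0.016),
                  n_pairs = 10)
  f <- fit_d14(m)
  expect_equal(f$slope, 0.04)
  expect_equal(f$d14, 0.01)
  # flat curve = pure localization noise
  m$msd <- rep(0.002, 4)
  f <- fit_d14(m)
  expect_equal(f$d14, 0)
  expect_equal(f$intercept, 0.002)
})

test_that("short trajectories are rejected with a clear error", {
  tr <- make_traj(1:4, 1:4)
  expect_error(compute_msd(tr, 0.16, 0.1), "too short")
})

test_that("intercept recovers four times the squared localization error", {
  set.seed(32)
  tr <- simulate_trajectories(2000, len = 50, d = 0.017, dt = 0.1,
                              sigma_loc = 0.02)
  dyn <- analyze_dynamics(tr, threshold = Inf)
  expect_equal(mean(dyn$intercept), 4 * 0.02^2, tolerance = 0.2)
})

test_that("D1-4 is unbiased on noise-free Brownian trajectories", {
  set.seed(33)
  tr <- simulate_trajectories(2000, len = 50, d = 0.017, dt = 0.1,
                              sigma_loc = 0)
  dyn <- analyze_dynamics(tr, threshold = Inf)
  expect_gt(mean(dyn$d14) / 0.017, 0.95)
  expect_lt(mean(dyn$d14) / 0.017, 1.05)
})

test_that("threshold calibration keeps the false-mobile rate near 5%", {
  set.seed(34)
  thr <- calibrate_immobile_threshold(n = 500, len = c(50, 200),
                                      sigma_loc = 0.02)
  tr <- simulate_trajectories(500, len = c(50, 200), d = 0,
                              sigma_loc = 0.02, mobile_frac = 0)
  dyn <- analyze_dynamics(tr, threshold = thr)
  fm <- mean(dyn$class == "mobile")
  expect_lt(fm, 0.10)  # 5% by construction, sampling noise allowed
})

test_that("an 80/20 mobile mixture is recovered within 5 points", {
  set.seed(35)
  tr <- simulate_trajectories(800, len = c(50, 300), d = 0.02,
                              sigma_loc = 0.02, mobile_frac = 0.8)
  thr <- calibrate_immobile_threshold(n = 800, len = c(50, 300),
                                      sigma_loc = 0.02)
  s <- population_summary(analyze_dynamics(tr, threshold = thr))
  true_immobile <- 100 * mean(!attr(tr, "truth_mobile"))
  expect_lt(abs(s$pct_immobile - true_immobile), 5)
})

test_that("population medians are computed on the mobile subset only", {
  dyn <- structure(data.frame(traj_id = 1:4, n_frames = 50,
                              d14 = c(0.0001, 0.02, 0.03, 0.04),
                              intercept = 0,
                              class = c("immobile", rep("mobile", 3))),
                   class = c("dynamics_result", "data.frame"))
  s <- population_summary(dyn)
  expect_equal(s$median_d14_mobile, 0.03)
  expect_equal(s$pct_mobile + s$pct_immobile, 100)
})

test_that("chi-square on mobility counts matches the brute-force formula", {
  a <- structure(list(label = "a", n = 1000, n_mobile = 820,
                      pct_mobile = 82, pct_immobile = 18,
                      median_d14_mobile = 0.017,
                      d14_mobile = rnorm(820, 0.017, 0.003)),
                 class = "population_summary")
  b <- structure(list(label = "b", n = 1000, n_mobile = 850,
                      pct_mobile = 85, pct_immobile = 15,
                      median_d14_mobile = 0.016,
                      d14_mobile = rnorm(850, 0.016, 0.003)),
                 class = "population_summary")
  cmp <- compare_populations(a, b)
  oracle <- chisq_2x2_oracle(rbind(c(820, 180), c(850, 150)))
  expect_equal(cmp$chisq, oracle, tolerance = 1e-10)
})

test_that("identical groups give a Mann-Whitney p near 1", {
  set.seed(36)
  d <- rnorm(200, 0.017, 0.003)
  mk <- function(lab) structure(
    list(label = lab, n = 250, n_mobile = 200, pct_mobile = 80,
         pct_immobile = 20, median_d14_mobile = median(d), d14_mobile = d),
    class = "population_summary")
  cmp <- compare_populations(mk("a"), mk("b"))
  expect_gt(cmp$mw_p, 0.99)
})

test_that("a 2x diffusion shift is detected at n = 500 per group", {
  set.seed(37)
  mk <- function(lab, mu) structure(
    list(label = lab, n = 600, n_mobile = 500, pct_mobile = 83,
         pct_immobile = 17, median_d14_mobile = mu,
         d14_mobile = rlnorm(500, log(mu), 0.6)),
    class = "population_summary")
  cmp <- compare_populations(mk("a", 0.017), mk("b", 0.034))
  expect_lte(cmp$mw_p, 0.001)
})
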
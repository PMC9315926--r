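test_that("MSI is the arithmetic mean of the first 20 intensities", {
  expect_equal(trajectory_msi(rep(100, 25)), 100)
  expect_equal(trajectory_msi(c(1:20, 500, 600)), 10.5)
  tr <- data.frame(traj_id = 1, frame = 19:0, intensity = c(500, rep(10, 19)))
  # ordering by frame matters: frame 0..18 are 10, frame 19 is 500
  expect_equal(trajectory_msi(tr), (19 * 10 + 500) / 20)
  expect_error(trajectory_msi(rep(1, 10)), "insufficient frames")
})

test_that("step counting finds clean steps and ignores flat traces", {
  tr <- c(rep(70, 50), rep(0, 50))
  expect_equal(count_bleach_steps(tr)$n_steps, 1L)
  expect_equal(count_bleach_steps(rep(50, 60))$n_steps, 0L)
  # two clean steps
  tr2 <- c(rep(140, 40), rep(70, 30), rep(0, 30))
  expect_equal(count_bleach_steps(tr2)$n_steps, 2L)
})

test_that("two-fluorophore traces yield two steps in most runs", {
  set.seed(41)
  hits <- 0; n <- 50
  for (i in seq_len(n)) {
    tr <- simulate_bleach_trace(2, n_frames = 150, bleach_rate = 0.15,
                                noise_sd = 5)
    if (tr$n_steps_true == 2 &&
        count_bleach_steps(tr$trace)$n_steps == 2) hits <- hits + 1
    if (tr$n_steps_true != 2) n <- n - 1
  }
  expect_gte(hits / n, 0.8)
})

test_that("monomer reference is recovered within 1% from clean samples", {
  set.seed(42)
  msi <- rnorm(1000, 69.33, 3.26)
  cal <- fit_monomer_reference(msi)
  expect_lt(abs(cal$mean - 69.33) / 69.33, 0.01)
  expect_lt(abs(cal$sd - 3.26) / 3.26, 0.3)
})

test_that("degenerate all-identical reference collapses to the value", {
  cal <- fit_monomer_reference(rep(50, 100))
  expect_equal(cal$mean, 50)
  expect_equal(cal$sd, 0)
})

test_that("a contaminated (bimodal) monomer reference warns", {
  set.seed(43)
  msi <- c(rnorm(400, 69, 3), rnorm(100, 138, 4))
  expect_warning(fit_monomer_reference(msi), "bimodal")
})

test_that("too few monomer particles is an error", {
  expect_error(fit_monomer_reference(rnorm(20, 69, 3)), ">= 50")
})

test_that("receptor number estimation rounds against the monomer unit", {
  cal <- list(mean = 69.33, sd = 3.26)
  r <- estimate_receptor_number(69.33, cal)
  expect_equal(r$n_hat, 1L)
  expect_equal(r$size_class, "<=2")
  r <- estimate_receptor_number(3.2 * 69.33, cal)
  expect_equal(r$n_hat, 3L)
  expect_equal(r$size_class, ">=3")
  # sub-monomer intensities clamp to 1
  expect_equal(estimate_receptor_number(10, cal)$n_hat, 1L)
  expect_error(estimate_receptor_number(-5, cal), "msi must be > 0")
})

test_that("nanocluster fractions sum to one and degenerate cases work", {
  cal <- list(mean = 69.33, sd = 3.26)
  all_mono <- analyze_stoichiometry(
    data.frame(traj_id = rep(1:3, each = 20),
               frame = rep(0:19, 3), intensity = 69), cal)
  s <- summarize_nanoclustering(list(g = all_mono))
  expect_equal(s$groups$frac_le2, 1)
  r <- estimate_receptor_number(c(138.7, 138.7, 277.3, 277.3), cal)
  r$traj_id <- 1:4
  s <- summarize_nanoclustering(list(g = r))
  expect_equal(s$groups$frac_le2, 0.5)
  expect_equal(s$groups$frac_ge3, 0.5)
  expect_equal(s$groups$frac_le2 + s$groups$frac_ge3, 1)
})

test_that("identical groups show no Tukey-significant MSI differences", {
  set.seed(44)
  mk <- function() {
    msi <- rnorm(150, 100, 20)
    r <- estimate_receptor_number(msi, list(mean = 69.33, sd = 3.26))
    r$traj_id <- seq_len(nrow(r))
    r
  }
  s <- summarize_nanoclustering(list(a = mk(), b = mk(), c = mk()))
  expect_true(all(s$tukey[, "p adj"] > 0.05))
})

test_that("oligomer size classes are recovered accurately from movies", {
  # rendered movies with sizes 1, 2, 4 at default noise
  cfg <- spt_sim_config(field_px = 96, n_frames = 30, density = 0.25,
                        oligomer_probs = c(0.4, 0.3, 0, 0.3),
                        mobile_frac = 0.5, bleach_rate = 0, seed = 45)
  sim <- simulate_spt_movie(cfg)
  trajs <- track_movie(sim$stack, psf_sigma = 1, min_length = 20)
  cal <- list(mean = 69.33, sd = 3.26)
  sto <- analyze_stoichiometry(trajs, cal)
  truth <- sim$truth[sim$truth$frame == 0, ]
  # match each trajectory to the nearest ground-truth particle
  match_n <- vapply(unique(sto$traj_id), function(id) {
    tr <- trajs[trajs$traj_id == id, ][1, ]
    tf <- sim$truth[sim$truth$frame == tr$frame, ]
    d <- sqrt((tf$x_px - tr$x)^2 + (tf$y_px - tr$y)^2)
    tf$oligomer_n[which.min(d)]
  }, 0)
  acc <- mean(sto$n_hat == match_n)
  expect_gt(acc, 0.9)
})
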
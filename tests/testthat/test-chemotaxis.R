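straight_track <- function(n = 11, dx = 2, dy = 0) {
  data.frame(cell_id = 1L, t_s = 120 * (0:(n - 1)),
             x_um = dx * (0:(n - 1)), y_um = dy * (0:(n - 1)))
}

test_that("a straight +x track has FMI and straightness exactly 1", {
  m <- track_metrics(straight_track())
  expect_identical(m$fmi_par, 1)
  expect_identical(m$straightness, 1)
  expect_equal(m$fmi_perp, 0)
})

test_that("a closed loop has zero straightness and zero FMI", {
  sq <- data.frame(cell_id = 1L, t_s = 120 * (0:4),
                   x_um = c(0, 10, 10, 0, 0), y_um = c(0, 0, 10, 10, 0))
  m <- track_metrics(sq)
  expect_equal(m$straightness, 0)
  expect_equal(m$fmi_par, 0)
  expect_equal(m$d_acc, 40)
})

test_that("the right-angle worked example matches hand geometry", {
  tr <- data.frame(cell_id = 1L, t_s = c(0, 120, 240),
                   x_um = c(0, 10, 10), y_um = c(0, 0, 10))
  m <- track_metrics(tr)
  expect_equal(m$d_acc, 20)
  expect_equal(m$d_eu, sqrt(200))
  expect_equal(m$straightness, sqrt(200) / 20)
  expect_equal(m$fmi_par, 0.5)
  expect_equal(m$fmi_perp, 0.5)
})

test_that("metric invariants hold on simulated walks", {
  tracks <- simulate_chemotaxis_tracks(
    chemotaxis_sim_config(n_cells = 50, n_steps = 40, beta = 0.3,
                          seed = 51))
  m <- track_metrics(tracks)
  expect_true(all(m$d_eu <= m$d_acc + 1e-12))
  expect_true(all(m$fmi_par^2 + m$fmi_perp^2 <=
                  m$straightness^2 + 1e-12))
  # rigid translation leaves metrics unchanged
  shifted <- tracks
  shifted$x_um <- shifted$x_um + 40
  shifted$y_um <- shifted$y_um - 13
  m2 <- track_metrics(shifted)
  expect_equal(m2$fmi_par, m$fmi_par)
  expect_equal(m2$straightness, m$straightness)
  # rotating tracks and axis together is equivariant
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- tracks
  xy <- as.matrix(tracks[c("x_um", "y_um")]) %*% t(R)
  rot$x_um <- xy[, 1]; rot$y_um <- xy[, 2]
  m3 <- track_metrics(rot, axis = as.vector(R %*% c(1, 0)))
  expect_equal(m3$fmi_par, m$fmi_par)
  expect_equal(m3$fmi_perp, m$fmi_perp)
})

test_that("maximal bias produces straight +x lines", {
  tracks <- simulate_chemotaxis_tracks(
    chemotaxis_sim_config(n_cells = 5, n_steps = 20, beta = 1,
                          speed_jitter = 0, seed = 52))
  m <- track_metrics(tracks)
  expect_equal(m$fmi_par, rep(1, 5))
  expect_equal(m$straightness, rep(1, 5))
})

test_that("unbiased walks have mean FMI and x-displacement near zero", {
  tracks <- simulate_chemotaxis_tracks(
    chemotaxis_sim_config(n_cells = 500, n_steps = 30, beta = 0,
                          seed = 53))
  m <- track_metrics(tracks)
  sem <- sd(m$fmi_par) / sqrt(nrow(m))
  expect_lt(abs(mean(m$fmi_par)), 2 * sem)
  semx <- sd(m$x_net) / sqrt(nrow(m))
  expect_lt(abs(mean(m$x_net)), 2.5 * semx)
})

test_that("stationary tracks are flagged and excluded", {
  tr <- data.frame(cell_id = 1L, t_s = c(0, 120, 240), x_um = 5, y_um = 5)
  m <- track_metrics(tr)
  expect_true(m$flagged)
  expect_true(is.na(m$fmi_par))
})

test_that("spider data are origin-translated and labelled by direction", {
  tr <- straight_track()
  tr$x_um <- tr$x_um + 5; tr$y_um <- tr$y_um + 5
  sp <- spider_plot_data(tr)
  expect_equal(sp$paths$x_um[1], 0)
  expect_equal(sp$paths$y_um[1], 0)
  expect_equal(sp$endpoints$label, "toward")
  back <- straight_track(dx = -2)
  expect_equal(spider_plot_data(back)$endpoints$label, "away")
})

test_that("toward fraction is near one half for unbiased walks", {
  tracks <- simulate_chemotaxis_tracks(
    chemotaxis_sim_config(n_cells = 200, n_steps = 25, beta = 0,
                          seed = 54))
  sp <- spider_plot_data(tracks)
  frac <- mean(sp$endpoints$label == "toward")
  ci <- 0.5 + c(-1, 1) * 3 * sqrt(0.25 / 200)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("biased and unbiased groups separate; identical groups do not", {
  mk <- function(beta, seed) track_metrics(simulate_chemotaxis_tracks(
    chemotaxis_sim_config(n_cells = 50, n_steps = 30, beta = beta,
                          seed = seed)))
  g0a <- mk(0, 55); g0b <- mk(0, 56); g5 <- mk(0.5, 57)
  null_cmp <- compare_conditions(list(a = g0a, b = g0b))
  expect_gt(null_cmp$anova_p_fmi, 0.05)
  cmp <- compare_conditions(list(ctrl = g0a, biased = g5))
  expect_lte(cmp$tukey_fmi[, "p adj"][1], 0.01)
  # three groups: only contrasts involving the shifted group significant
  cmp3 <- compare_conditions(list(a = g0a, b = g0b, c = g5))
  p <- cmp3$tukey_fmi[, "p adj"]
  expect_gt(p["b-a"], 0.05)
  expect_lt(p["c-a"], 0.01)
  expect_lt(p["c-b"], 0.01)
})
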
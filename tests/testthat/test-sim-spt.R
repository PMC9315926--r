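test_that("noise-free immobile monomer renders at the calibrated intensity", {
  cfg <- spt_sim_config(field_px = 32, n_frames = 3, density = 1 / (32 * 0.16)^2,
                        oligomer_probs = 1, mobile_frac = 0, monomer_sd = 0,
                        read_noise_sd = 0, shot_noise = FALSE,
                        camera_baseline = 0, bleach_rate = 0, seed = 1)
  sim <- simulate_spt_movie(cfg)
  # centroid constant across frames
  expect_equal(sim$truth$x_px, rep(sim$truth$x_px[1], 3))
  expect_equal(sim$truth$y_px, rep(sim$truth$y_px[1], 3))
  # frame-0 integrated intensity ~ monomer mean (PSF tails may clip edges)
  expect_equal(sum(sim$stack$frames[, , 1]), 69.33, tolerance = 0.01)
})

test_that("without bleaching a tetramer keeps its intensity for the whole movie", {
  cfg <- spt_sim_config(field_px = 32, n_frames = 50,
                        density = 1 / (32 * 0.16)^2,
                        oligomer_probs = c(0, 0, 0, 1), mobile_frac = 0,
                        read_noise_sd = 0, shot_noise = FALSE,
                        camera_baseline = 0, bleach_rate = 0, seed = 2)
  sim <- simulate_spt_movie(cfg)
  expect_true(all(sim$truth$fluors_alive == 4))
  expect_equal(length(unique(sim$truth$intensity)), 1L)
})

test_that("mean squared step matches 4 D dt over many steps", {
  cfg <- spt_sim_config(field_px = 128, n_frames = 200, density = 0.35,
                        d_mobile = 0.017, mobile_frac = 1, seed = 3)
  sim <- simulate_spt_movie(cfg)
  tr <- sim$truth[order(sim$truth$particle_id, sim$truth$frame), ]
  px <- cfg$pixel_size
  d2 <- unlist(lapply(split(tr, tr$particle_id), function(p) {
    (diff(p$x_px * px))^2 + (diff(p$y_px * px))^2
  }))
  expect_gt(length(d2), 1e4)
  expect_equal(mean(d2), 4 * 0.017 * 0.1, tolerance = 0.05)
})

test_that("a field too sparse to hold one particle is an error", {
  expect_error(simulate_spt_movie(spt_sim_config(field_px = 16,
                                                 density = 0.01)),
               "empty field")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(spt_sim_config(density = 5), "4.5")
  expect_error(spt_sim_config(oligomer_probs = c(0.5, 0.4)), "sum to 1")
  expect_error(spt_sim_config(bleach_rate = -1))
  expect_error(spt_sim_config(mobile_frac = 1.5))
})

test_that("seeded runs are bit-reproducible", {
  a <- simulate_spt_movie(spt_sim_config(field_px = 32, n_frames = 5,
                                         density = 0.5, seed = 9))
  b <- simulate_spt_movie(spt_sim_config(field_px = 32, n_frames = 5,
                                         density = 0.5, seed = 9))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
})

test_that("localizing a noise-free movie recovers true positions", {
  sim <- sim_small_movie(seed = 5)
  truth0 <- sim$truth[sim$truth$frame == 0, ]
  det <- detect_spots(sim$stack$frames[, , 1], psf_sigma = 1,
                      snr_threshold = 5)
  # interior, resolved particles only (detection excludes a border
  # margin, and overlapping spots merge by design)
  inner <- truth0[truth0$x_px > 4 & truth0$x_px < 59 &
                  truth0$y_px > 4 & truth0$y_px < 59, ]
  nn <- as.matrix(dist(truth0[, c("x_px", "y_px")]))
  diag(nn) <- Inf
  resolved <- rownames(truth0)[apply(nn, 1, min) > 5]
  inner <- inner[rownames(inner) %in% resolved, ]
  errs <- vapply(seq_len(nrow(inner)), function(i) {
    min(sqrt((det$x - inner$x_px[i])^2 + (det$y - inner$y_px[i])^2))
  }, 0)
  expect_true(all(errs < 0.02))
})

test_that("simulated bleach traces count their true fluorophore losses", {
  set.seed(11)
  tr <- simulate_bleach_trace(1, n_frames = 100, bleach_rate = 0.5,
                              noise_sd = 0)
  expect_equal(tr$alive[1], 1L)
  expect_true(all(diff(tr$alive) <= 0))
})
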
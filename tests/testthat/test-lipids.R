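test_that("normalization cancels per-sample drift and routes by ion mode", {
  cfg <- lipid_sim_config(n_species = 8, drift_sd = 0.5, seed = 61)
  tab <- simulate_lipid_table(cfg)
  norm <- normalize_internal_standard(tab)
  sp <- lipid_species(tab)
  # manual check: each species divided by its own mode's IS column
  ion <- attr(tab, "ion_mode")
  for (s in sp[c(1, 2)]) {
    is_col <- if (ion[s] == "positive") "IS_pos" else "IS_neg"
    expect_equal(norm[[s]], tab[[s]] / tab[[is_col]])
  }
})

test_that("normalization is invariant to rescaling one sample", {
  tab <- simulate_lipid_table(lipid_sim_config(n_species = 6, seed = 62))
  tab2 <- tab
  sp <- c("IS_pos", "IS_neg", lipid_species(tab))
  tab2[3, sp] <- tab2[3, sp] * 7.3
  n1 <- normalize_internal_standard(tab)
  n2 <- normalize_internal_standard(tab2)
  expect_equal(n2[lipid_species(tab)], n1[lipid_species(tab)])
})

test_that("a zero internal standard names the offending sample", {
  tab <- simulate_lipid_table(lipid_sim_config(n_species = 4, seed = 63))
  tab$IS_pos[2] <- 0
  expect_error(normalize_internal_standard(tab), tab$sample[2])
})

test_that("drift biases fold changes unless normalized away", {
  # one group gets systematically doubled signals (instrument drift)
  cfg <- lipid_sim_config(n_species = 10, fold_changes = 1, bio_cv = 0.01,
                          tech_cv = 0.01, drift_sd = 0, seed = 64)
  tab <- simulate_lipid_table(cfg)
  sp <- lipid_species(tab)
  treated_rows <- tab$group == "treated"
  tab[treated_rows, c("IS_pos", "IS_neg", sp)] <-
    tab[treated_rows, c("IS_pos", "IS_neg", sp)] * 2
  norm <- normalize_internal_standard(tab)
  raw_fc <- mean(tab[treated_rows, sp[1]]) / mean(tab[tab$group == "control", sp[1]])
  norm_fc <- mean(norm[treated_rows, sp[1]]) / mean(norm[norm$group == "control", sp[1]])
  expect_gt(raw_fc, 1.8)
  expect_equal(norm_fc, 1, tolerance = 0.05)
})

test_that("QC CV filter keeps clean species and drops noisy ones", {
  cfg <- lipid_sim_config(n_species = 10,
                          qc_cv = c(rep(0.03, 9), 0.15), seed = 65)
  tab <- normalize_internal_standard(simulate_lipid_table(cfg))
  filt <- qc_cv_filter(tab, threshold = 10)
  rep_ <- attr(filt, "cv_report")
  expect_false(rep_$retained[10])
  expect_true(all(rep_$retained[1:9]))
  # identical QC rows: zero CV, everything retained
  tab0 <- tab
  qc_rows <- which(tab0$group == "QC")
  for (s in lipid_species(tab)) tab0[qc_rows, s] <- 1
  expect_true(all(attr(qc_cv_filter(tab0), "cv_report")$retained))
  # permissive threshold retains everything
  expect_true(all(attr(qc_cv_filter(tab, threshold = 100),
                       "cv_report")$retained))
})

test_that("complete separation at 5 vs 5 gives the exact p = 2/252", {
  x <- c(1, 2, 3, 4, 5); y <- c(10, 11, 12, 13, 14)
  p <- wilcox.test(y, x, exact = TRUE)$p.value
  expect_equal(p, 2 / 252, tolerance = 1e-12)
  expect_equal(mw_exact_oracle(x, y), 2 / 252, tolerance = 1e-12)
})

test_that("planted fold changes are detected and estimated", {
  # several up-regulated species, as in a lipid-class-wide perturbation;
  # with n = 5 exact rank tests the smallest attainable p is 2/252, so a
  # single changed species among many could never clear an FDR of 0.05
  cfg <- lipid_sim_config(n_species = 20,
                          fold_changes = c(rep(8, 5), rep(1, 15)),
                          bio_cv = 0.1, seed = 66)
  res <- lipid_stats_pipeline(simulate_lipid_table(cfg))
  expect_true(all(res$significant[1:5]))
  expect_lt(abs(mean(res$fc[1:5]) - 8) / 8, 0.25)
  expect_equal(res$log2fc, log2(res$fc))
})

test_that("BH q-values match the brute-force step-up oracle", {
  set.seed(67)
  p <- c(runif(30)^2, runif(10))
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-10)
  cfg <- lipid_sim_config(n_species = 12, seed = 68)
  res <- lipid_stats_pipeline(simulate_lipid_table(cfg))
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-10)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("the QC filter operates on normalized intensities", {
  # drift inflates raw QC CV; normalization must remove it before the CV
  cfg <- lipid_sim_config(n_species = 6, qc_cv = 0.02, drift_sd = 0.4,
                          seed = 69)
  tab <- simulate_lipid_table(cfg)
  qc <- tab[tab$group == "QC", ]
  raw_cv <- 100 * sd(qc[[lipid_species(tab)[1]]]) /
    mean(qc[[lipid_species(tab)[1]]])
  expect_gt(raw_cv, 10)  # would fail the filter if computed on raw data
  res <- lipid_stats_pipeline(tab)
  expect_true(lipid_species(tab)[1] %in% res$species)
})

test_that("all-tied species get p = 1 with a warning", {
  cfg <- lipid_sim_config(n_species = 4, seed = 70)
  tab <- normalize_internal_standard(simulate_lipid_table(cfg))
  sp <- lipid_species(tab)[1]
  tab[[sp]] <- 1
  expect_warning(res <- lipid_group_test(tab), "tied")
  expect_equal(res$p[res$species == sp], 1)
})
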
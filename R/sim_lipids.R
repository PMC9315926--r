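#' Configuration for the lipid feature-table simulator
#'
#' Emulates an annotated LC-MS lipidomics feature matrix: log-normal
#' species intensities for control and treated groups (n biological
#' replicates measured in technical duplicates), per-ion-mode internal
#' standards whose intensity carries a per-sample multiplicative drift
#' shared by every feature of that sample, pooled QC injections with a
#' controllable intra-QC coefficient of variation, and planted fold
#' changes between groups for chosen species.
#'
#' @param n_per_group biological replicates per group (default 5).
#' @param n_duplicates technical duplicates per biological replicate.
#' @param n_species number of annotated lipid species.
#' @param fold_changes numeric vector of treated/control fold changes, one
#'   per species (recycled); 1 = null species. Must be > 0.
#' @param base_mean_log,base_sd_log log-scale mean and sd of species base
#'   intensities.
#' @param bio_cv biological coefficient of variation within a group.
#' @param tech_cv technical (duplicate-level) coefficient of variation.
#' @param is_intensity internal standard intensity (same for both modes).
#' @param drift_sd log-scale sd of the per-sample multiplicative drift
#'   applied to all features (species and internal standards) of a sample.
#' @param n_qc number of pooled QC injections (>= 3 needed for filtering).
#' @param qc_cv intra-QC coefficient of variation; a scalar or one value
#'   per species (so individual species can be planted to fail the filter).
#' @param seed integer seed.
#' @return A validated config list of class `lipid_sim_config`.
#' @export
lipid_sim_config <- function(n_per_group = 5, n_duplicates = 2,
                             n_species = 40, fold_changes = 1,
                             base_mean_log = log(1e5), base_sd_log = 0.8,
                             bio_cv = 0.15, tech_cv = 0.05,
                             is_intensity = 5e4, drift_sd = 0.2,
                             n_qc = 5, qc_cv = 0.05, seed = 1L) {
  fc <- rep_len(fold_changes, n_species)
  qcv <- rep_len(qc_cv, n_species)
  if (any(fc <= 0)) stop("fold changes must be > 0")
  if (any(qcv < 0) || bio_cv < 0 || tech_cv < 0) stop("CVs must be >= 0")
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_duplicates = as.integer(n_duplicates),
              n_species = as.integer(n_species), fold_changes = fc,
              base_mean_log = base_mean_log, base_sd_log = base_sd_log,
              bio_cv = bio_cv, tech_cv = tech_cv,
              is_intensity = is_intensity, drift_sd = drift_sd,
              n_qc = as.integer(n_qc), qc_cv = qcv, seed = as.integer(seed))
  class(cfg) <- "lipid_sim_config"
  cfg
}

#' Simulate a samples x lipid-species feature table
#'
#' Half of the species are assigned to positive ion mode (sphinganine-like
#' internal standard column `IS_pos`) and half to negative mode
#' (`IS_neg`). QC rows are pooled means of all biological samples with
#' multiplicative intra-QC noise.
#'
#' @param config a [lipid_sim_config()].
#' @return A `lipid_table`: a data frame with columns `sample`, `group`
#'   (`control`, `treated` or `QC`), `replicate`, the two internal-standard
#'   columns and one column per species; attribute `ion_mode` is a named
#'   character vector (`"positive"`/`"negative"`) over species and
#'   `truth_fc` the planted fold changes.
#' @export
simulate_lipid_table <- function(config = lipid_sim_config()) {
  stopifnot(inherits(config, "lipid_sim_config"))
  set.seed(config$seed)
  ns <- config$n_species
  species <- sprintf("species_%02d", seq_len(ns))
  ion_mode <- setNames(rep(c("positive", "negative"), length.out = ns),
                       species)
  base <- exp(rnorm(ns, config$base_mean_log, config$base_sd_log))

  grp_fc <- list(control = rep(1, ns), treated = config$fold_changes)
  rows <- list(); meta <- list(); k <- 0
  cv2sd <- function(cv) sqrt(log(1 + cv^2))
  for (g in names(grp_fc)) {
    for (b in seq_len(config$n_per_group)) {
      # biological level per replicate
      bio <- base * grp_fc[[g]] *
        exp(rnorm(ns, -cv2sd(config$bio_cv)^2 / 2, cv2sd(config$bio_cv)))
      for (d in seq_len(config$n_duplicates)) {
        k <- k + 1
        drift <- exp(rnorm(1, 0, config$drift_sd))
        tech <- exp(rnorm(ns, -cv2sd(config$tech_cv)^2 / 2,
                          cv2sd(config$tech_cv)))
        rows[[k]] <- c(IS_pos = config$is_intensity * drift,
                       IS_neg = config$is_intensity * drift,
                       setNames(bio * tech * drift, species))
        meta[[k]] <- data.frame(sample = sprintf("%s_%d_%d", g, b, d),
                                group = g, replicate = b)
      }
    }
  }
  pooled <- base * (1 + config$fold_changes) / 2
  sd_qc <- cv2sd(config$qc_cv)
  for (q in seq_len(config$n_qc)) {
    k <- k + 1
    drift <- exp(rnorm(1, 0, config$drift_sd))
    noise <- exp(rnorm(ns, -sd_qc^2 / 2, sd_qc))
    rows[[k]] <- c(IS_pos = config$is_intensity * drift,
                   IS_neg = config$is_intensity * drift,
                   setNames(pooled * noise * drift, species))
    meta[[k]] <- data.frame(sample = sprintf("QC_%d", q), group = "QC",
                            replicate = q)
  }
  tab <- cbind(do.call(rbind, meta),
               as.data.frame(do.call(rbind, rows)))
  rownames(tab) <- NULL
  attr(tab, "ion_mode") <- ion_mode
  attr(tab, "is_cols") <- c(positive = "IS_pos", negative = "IS_neg")
  attr(tab, "truth_fc") <- setNames(config$fold_changes, species)
  class(tab) <- c("lipid_table", "data.frame")
  tab
}

#' Species columns of a lipid table
#' @param table a `lipid_table`.
#' @return Character vector of species column names.
#' @export
lipid_species <- function(table) names(attr(table, "ion_mode"))
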
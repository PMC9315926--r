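#' Internal-standard normalization of a lipid feature table
#'
#' Each species intensity is divided by the intensity, in the same
#' sample, of the internal standard of that species' ion mode
#' (sphinganine-like standard for positive mode, deuterated palmitic
#' acid-like for negative mode). This cancels per-sample multiplicative
#' effects from preparation and the analytical run.
#'
#' @param table a `lipid_table` (see [simulate_lipid_table()] /
#'   [read_lipid_csv()]).
#' @return The table with species columns normalized (internal-standard
#'   columns kept untouched) and attribute `normalized = TRUE`.
#' @export
normalize_internal_standard <- function(table) {
  ion <- attr(table, "ion_mode")
  is_cols <- attr(table, "is_cols")
  stopifnot(!is.null(ion), !is.null(is_cols))
  for (mode in names(is_cols)) {
    is_v <- table[[is_cols[[mode]]]]
    if (any(is_v <= 0)) {
      bad <- table$sample[which(is_v <= 0)[1]]
      stop("internal standard (", mode, " mode) is zero in sample ", bad)
    }
    sp <- names(ion)[ion == mode]
    for (s in sp) table[[s]] <- table[[s]] / is_v
  }
  attr(table, "normalized") <- TRUE
  table
}

#' QC-based coefficient-of-variation filter
#'
#' The CV (100 sd / mean) of each species across pooled QC injections is
#' computed on normalized intensities; species at or above the threshold
#' are dropped. Species with zero QC mean are dropped with a `zero-QC`
#' flag.
#'
#' @param table a normalized `lipid_table` with >= 3 QC rows.
#' @param threshold CV threshold in percent (default 10, the conventional
#'   cutoff for well-behaved features).
#' @return The filtered table; attribute `cv_report` is a data frame
#'   (`species`, `cv`, `retained`, `flag`).
#' @export
qc_cv_filter <- function(table, threshold = 10) {
  if (!isTRUE(attr(table, "normalized")))
    warning("qc_cv_filter called on non-normalized table")
  qc <- table[table$group == "QC", , drop = FALSE]
  if (nrow(qc) < 3) stop("need >= 3 QC rows for the CV filter")
  ion <- attr(table, "ion_mode")
  species <- names(ion)
  cv <- vapply(species, function(s) {
    m <- mean(qc[[s]])
    if (m == 0) return(NA_real_)
    100 * sd(qc[[s]]) / m
  }, 0)
  flag <- ifelse(is.na(cv), "zero-QC", "")
  retained <- !is.na(cv) & cv < threshold
  report <- data.frame(species = species, cv = cv, retained = retained,
                       flag = flag, row.names = NULL)
  dropped <- species[!retained]
  out <- table[, !(names(table) %in% dropped), drop = FALSE]
  attr(out, "ion_mode") <- ion[retained]
  attr(out, "is_cols") <- attr(table, "is_cols")
  attr(out, "normalized") <- attr(table, "normalized")
  attr(out, "cv_report") <- report
  class(out) <- class(table)
  out
}

#' Group testing of lipid species
#'
#' Per species: Shapiro-Wilk normality p per group (reported, not used to
#' gate the test), a two-sided Mann-Whitney U test (exact when sample
#' sizes allow and there are no ties), Benjamini-Hochberg adjustment
#' across all tested species, and the fold change
#' mean(treated)/mean(control) of normalized intensities (log2 fold
#' change also emitted). Technical duplicates are averaged per biological
#' replicate before testing, so the test units are biological samples.
#'
#' @param table a normalized, QC-filtered `lipid_table`.
#' @param control,treated group labels.
#' @param alpha significance level applied to both raw p and BH q.
#' @param average_duplicates average technical duplicates per biological
#'   replicate first (recommended; avoids pseudo-replication).
#' @return A `lipid_results` data frame: `species`, `ion_mode`, `fc`,
#'   `log2fc`, `p`, `q`, `shapiro_p_control`, `shapiro_p_treated`,
#'   `significant`.
#' @export
lipid_group_test <- function(table, control = "control",
                             treated = "treated", alpha = 0.05,
                             average_duplicates = TRUE) {
  ion <- attr(table, "ion_mode")
  species <- names(ion)
  get_group <- function(g) {
    d <- table[table$group == g, , drop = FALSE]
    if (nrow(d) == 0) stop("no samples with group label '", g, "'")
    if (average_duplicates && anyDuplicated(d$replicate)) {
      split_d <- split(d[species], d$replicate)
      d <- do.call(rbind, lapply(split_d, colMeans))
      as.data.frame(d)
    } else d[species]
  }
  a <- get_group(control)
  b <- get_group(treated)
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("need >= 3 test units per group after duplicate averaging")
  rows <- lapply(species, function(s) {
    x <- a[[s]]; y <- b[[s]]
    tied <- length(unique(c(x, y))) == 1
    if (tied) {
      warning("all values tied for ", s, "; p set to 1")
      p <- 1
    } else {
      p <- tryCatch(
        wilcox.test(y, x, alternative = "two.sided", exact = TRUE)$p.value,
        warning = function(w)
          suppressWarnings(wilcox.test(y, x, exact = FALSE)$p.value))
    }
    swp <- function(v) if (length(unique(v)) < 3) NA_real_
                       else shapiro.test(v)$p.value
    fc <- mean(y) / mean(x)
    data.frame(species = s, ion_mode = unname(ion[s]), fc = fc,
               log2fc = log2(fc), p = p,
               shapiro_p_control = swp(x), shapiro_p_treated = swp(y))
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$p <= alpha & res$q <= alpha
  res <- res[, c("species", "ion_mode", "fc", "log2fc", "p", "q",
                 "shapiro_p_control", "shapiro_p_treated", "significant")]
  rownames(res) <- NULL
  class(res) <- c("lipid_results", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' Run the full lipid statistics pipeline
#'
#' Fixed order: internal-standard normalization, then the QC CV filter
#' (on normalized values), then group testing.
#'
#' @param table a raw `lipid_table`.
#' @param control,treated group labels.
#' @param alpha significance level.
#' @param cv_threshold QC CV threshold, percent.
#' @return A `lipid_results` data frame (see [lipid_group_test()]);
#'   attribute `cv_report` carries the filter report.
#' @export
lipid_stats_pipeline <- function(table, control = "control",
                                 treated = "treated", alpha = 0.05,
                                 cv_threshold = 10) {
  norm <- normalize_internal_standard(table)
  filt <- qc_cv_filter(norm, threshold = cv_threshold)
  res <- lipid_group_test(filt, control, treated, alpha)
  attr(res, "cv_report") <- attr(filt, "cv_report")
  res
}
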
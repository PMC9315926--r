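#' Mean spot intensity of a trajectory
#'
#' Arithmetic mean of the background-subtracted integrated intensities of
#' the first `first_n` detections (by default the first 20 frames, the
#' window over which fluorophore loss to photobleaching is still small).
#'
#' @param traj data frame with an `intensity` column for one trajectory
#'   (ordered by frame), or a bare numeric intensity vector.
#' @param first_n number of leading frames to average.
#' @return MSI in a.u.
#' @export
trajectory_msi <- function(traj, first_n = 20) {
  v <- if (is.data.frame(traj)) {
    traj <- traj[order(traj$frame), ]
    traj$intensity
  } else as.numeric(traj)
  if (length(v) < first_n)
    stop("insufficient frames for MSI (need >= ", first_n, ")")
  mean(v[seq_len(first_n)])
}

#' Count photobleaching steps in an intensity trace
#'
#' Greedy step fitting: starting from a single-segment (constant) model,
#' the changepoint that maximally reduces the residual sum of squares is
#' added while the reduction exceeds a BIC-style penalty. The noise
#' variance in the penalty is estimated robustly from first differences
#' of the trace. Returns the number of downward steps in the fitted
#' piecewise-constant trace.
#'
#' @param trace numeric intensity time series (length >= 20).
#' @param penalty per-step penalty on the residual sum of squares;
#'   defaults to `2 * sigma^2 * log(n)` with sigma from first differences.
#' @param min_seg minimum segment length in frames.
#' @return List: `n_steps` (downward steps), `changepoints` (frame indices
#'   after which the level changes), `levels` (fitted segment means).
#' @export
count_bleach_steps <- function(trace, penalty = NULL, min_seg = 3) {
  n <- length(trace)
  if (n < 20) stop("trace too short (need >= 20 frames)")
  if (is.null(penalty)) {
    sig <- mad(diff(trace)) / sqrt(2)
    sig <- max(sig, 1e-6 * max(abs(range(trace)), 1))
    penalty <- 2 * sig^2 * log(n)
  }
  bounds <- c(0L, n)  # segment boundaries (changepoint after index b)
  seg_rss <- function(a, b) {
    v <- trace[(a + 1):b]
    sum((v - mean(v))^2)
  }
  best_split <- function(a, b) {
    # best single changepoint inside (a, b]; O(len) with running sums
    v <- trace[(a + 1):b]
    m <- length(v)
    if (m < 2 * min_seg) return(NULL)
    cs <- cumsum(v); cs2 <- cumsum(v^2)
    k <- min_seg:(m - min_seg)
    rss_l <- cs2[k] - cs[k]^2 / k
    rss_r <- (cs2[m] - cs2[k]) - (cs[m] - cs[k])^2 / (m - k)
    tot <- rss_l + rss_r
    i <- which.min(tot)
    list(cp = a + k[i], rss = tot[i])
  }
  rss_now <- sum(vapply(seq_len(length(bounds) - 1), function(i)
    seg_rss(bounds[i], bounds[i + 1]), 0))
  repeat {
    cand <- NULL
    for (i in seq_len(length(bounds) - 1)) {
      s <- best_split(bounds[i], bounds[i + 1])
      if (is.null(s)) next
      gain <- seg_rss(bounds[i], bounds[i + 1]) - s$rss
      if (is.null(cand) || gain > cand$gain)
        cand <- list(cp = s$cp, gain = gain)
    }
    if (is.null(cand) || cand$gain <= penalty || cand$gain <= 1e-12) break
    bounds <- sort(c(bounds, cand$cp))
  }
  levels <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(trace[(bounds[i] + 1):bounds[i + 1]]), 0)
  down <- sum(diff(levels) < 0)
  list(n_steps = down, changepoints = bounds[-c(1, length(bounds))],
       levels = levels)
}

#' Fit the monomer intensity reference
#'
#' Least-squares Gaussian fit to the histogram of validated monomer MSI
#' values (bin width by Freedman-Diaconis). A Gaussian-mixture BIC check
#' (1 vs 2 components) warns when the reference distribution looks
#' bimodal, i.e. contaminated with higher oligomers.
#'
#' @param msi numeric MSI values of validated monomeric particles
#'   (single-bleach-step traces or a monomer-control construct); >= 50
#'   values required.
#' @return A `monomer_calibration` list: `mean`, `sd`, `n`, `r_squared`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_monomer_reference <- function(msi) {
  msi <- msi[is.finite(msi)]
  if (length(msi) < 50)
    stop("need >= 50 validated monomer particles for calibration")
  if (sd(msi) < .Machine$double.eps^0.5 * max(abs(msi), 1)) {
    # degenerate: all values identical up to rounding
    return(structure(list(mean = mean(msi), sd = 0, n = length(msi),
                          r_squared = 1), class = "monomer_calibration"))
  }
  # bimodality check on the raw sample: a 2-component Gaussian mixture
  # clearly preferred by BIC means the reference contains oligomers
  bic1 <- Mclust(msi, G = 1, modelNames = "V", verbose = FALSE)$bic
  bic2 <- tryCatch(
    Mclust(msi, G = 2, modelNames = "V", verbose = FALSE)$bic,
    error = function(e) -Inf)
  if (is.numeric(bic2) && length(bic2) == 1 && bic2 > bic1 + 10)
    warning("contaminated monomer reference: intensity distribution is bimodal")
  # gross outliers (overlapping particles, failed fits) would wreck the
  # histogram fit; the Gaussian model only describes the central mode
  ctr <- median(msi)
  scl <- mad(msi)
  if (scl > 0) msi <- msi[abs(msi - ctr) <= 5 * scl]

  h <- graphics::hist(msi, breaks = "FD", plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(A = max(h$counts), mu = mean(msi), s = sd(msi))
  fit <- tryCatch(
    nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df, start = start,
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    mu <- mean(msi); s <- sd(msi); r2 <- NA_real_
  } else {
    cf <- coef(fit)
    mu <- unname(cf["mu"]); s <- abs(unname(cf["s"]))
    r2 <- 1 - sum(resid(fit)^2) / sum((df$y - mean(df$y))^2)
  }
  # sd cannot resolve below the histogram bin width
  s <- max(s, diff(h$mids[1:2]) / 2)
  structure(list(mean = mu, sd = s, n = length(msi), r_squared = r2),
            class = "monomer_calibration")
}

#' @export
print.monomer_calibration <- function(x, ...) {
  cat(sprintf("<monomer_calibration> mean %.2f +/- %.2f a.u. (n = %d, R2 = %.3f)\n",
              x$mean, x$sd, x$n, x$r_squared))
  invisible(x)
}

#' Estimate receptors per particle from MSI
#'
#' n_hat = max(1, round(msi / monomer mean)); particles with n_hat <= 2
#' are classed as monomers/dimers (`"<=2"`), n_hat >= 3 as nanoclusters
#' (`">=3"`). Rounding (rather than flooring) keeps the error symmetric
#' around integer stoichiometries.
#'
#' @param msi numeric MSI values, a.u. (> 0).
#' @param cal a `monomer_calibration` (or a list with `$mean`).
#' @return Data frame with `msi`, `n_hat`, `size_class`.
#' @export
estimate_receptor_number <- function(msi, cal) {
  if (any(msi <= 0)) stop("msi must be > 0")
  stopifnot(cal$mean > 0)
  n_hat <- pmax(1L, as.integer(round(msi / cal$mean)))
  data.frame(msi = msi, n_hat = n_hat,
             size_class = ifelse(n_hat >= 3, ">=3", "<=2"))
}

#' Per-trajectory stoichiometry for a tracked dataset
#'
#' @param trajs a `trajectories` data frame with intensities.
#' @param cal a `monomer_calibration`.
#' @param first_n frames averaged for the MSI.
#' @return A `stoichiometry_result` data frame: `traj_id`, `msi`,
#'   `n_hat`, `size_class`.
#' @export
analyze_stoichiometry <- function(trajs, cal, first_n = 20) {
  parts <- split(trajs[c("traj_id", "frame", "intensity")], trajs$traj_id)
  ids <- vapply(parts, function(tr) tr$traj_id[1], 0)
  msi <- vapply(parts, function(tr) {
    if (nrow(tr) < first_n) return(NA_real_)
    trajectory_msi(tr, first_n)
  }, 0)
  keep <- is.finite(msi) & msi > 0
  res <- cbind(traj_id = unname(ids[keep]),
               estimate_receptor_number(unname(msi[keep]), cal))
  class(res) <- c("stoichiometry_result", "data.frame")
  res
}

#' Select monomer MSI values by single-bleach-step validation
#'
#' Scans trajectory intensity traces, keeps those whose trace shows
#' exactly one downward photobleaching step, and returns their MSI
#' values; these serve as a self-calibrated monomer reference when no
#' monomer-control dataset is available.
#'
#' @param trajs a `trajectories` data frame with intensities.
#' @param first_n frames averaged for the MSI.
#' @param ... passed to [count_bleach_steps()].
#' @return Numeric vector of monomer MSI values.
#' @export
select_monomer_msi <- function(trajs, first_n = 20, ...) {
  out <- numeric(0)
  for (tr in split(trajs[c("traj_id", "frame", "intensity")],
                   trajs$traj_id)) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < first_n) next
    st <- tryCatch(count_bleach_steps(tr$intensity, ...),
                   error = function(e) NULL)
    if (!is.null(st) && st$n_steps == 1)
      out <- c(out, trajectory_msi(tr, first_n))
  }
  out
}

#' Summarize nanoclustering per group and compare groups
#'
#' Per group: fraction of particles with n_hat <= 2 and >= 3 (summing to
#' 1) and the mean MSI. Across groups: chi-square on the size-class
#' counts and one-way ANOVA with Tukey's multiple comparison test on the
#' MSI values.
#'
#' @param results named list of `stoichiometry_result` data frames, one
#'   per group.
#' @return A `nanoclustering_summary` list: per-group table (`n`,
#'   `frac_le2`, `frac_ge3`, `mean_msi`) and, for >= 2 groups, `chisq_p`
#'   and `tukey` (matrix of adjusted p-values and differences for MSI).
#' @export
summarize_nanoclustering <- function(results) {
  if (!is.list(results) || is.data.frame(results))
    results <- list(group = results)
  groups <- names(results)
  per <- do.call(rbind, lapply(groups, function(g) {
    r <- results[[g]]
    data.frame(group = g, n = nrow(r),
               frac_le2 = mean(r$size_class == "<=2"),
               frac_ge3 = mean(r$size_class == ">=3"),
               mean_msi = mean(r$msi))
  }))
  out <- list(groups = per)
  if (length(groups) >= 2) {
    counts <- t(vapply(groups, function(g) {
      r <- results[[g]]
      c(le2 = sum(r$size_class == "<=2"), ge3 = sum(r$size_class == ">=3"))
    }, c(le2 = 0, ge3 = 0)))
    cs <- suppressWarnings(chisq.test(counts, correct = FALSE))
    long <- do.call(rbind, lapply(groups, function(g)
      data.frame(group = g, msi = results[[g]]$msi)))
    long$group <- factor(long$group)
    av <- aov(msi ~ group, data = long)
    out$chisq <- unname(cs$statistic)
    out$chisq_p <- cs$p.value
    out$anova_p <- summary(av)[[1]][["Pr(>F)"]][1]
    out$tukey <- TukeyHSD(av)$group
  }
  class(out) <- "nanoclustering_summary"
  out
}

#' @export
print.nanoclustering_summary <- function(x, ...) {
  cat("<nanoclustering_summary>\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$chisq_p))
    cat(sprintf("  chi-square p = %.4g (class counts); ANOVA p = %.4g (MSI)\n",
                x$chisq_p, x$anova_p))
  invisible(x)
}
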
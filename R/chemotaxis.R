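#' Directionality metrics for cell-centroid tracks
#'
#' Per cell: accumulated path length d_acc, Euclidean end-to-end distance
#' d_eu, net displacement along and across the gradient axis, forward
#' migration indices FMI_par = x_net / d_acc and FMI_perp = y_net / d_acc
#' (Ibidi convention), and straightness = d_eu / d_acc. Stationary tracks
#' (d_acc = 0) have undefined metrics; they are flagged and excluded from
#' group statistics.
#'
#' @param tracks a `cell_tracks` data frame (`cell_id`, `t_s`, `x_um`,
#'   `y_um`), e.g. from [simulate_chemotaxis_tracks()] or
#'   [read_tracks_csv()].
#' @param axis gradient axis as a 2-vector (default `c(1, 0)`, i.e. +x,
#'   the side the chemoattractant is added to); tracks recorded in other
#'   orientations are rotated, not re-coded.
#' @return A `chemotaxis_metrics` data frame: `cell_id`, `n_steps`,
#'   `d_acc`, `d_eu`, `x_net`, `y_net`, `fmi_par`, `fmi_perp`,
#'   `straightness`, `flagged`.
#' @export
track_metrics <- function(tracks, axis = attr(tracks, "gradient_axis")) {
  stopifnot(all(c("cell_id", "t_s", "x_um", "y_um") %in% names(tracks)))
  if (is.null(axis)) axis <- c(1, 0)
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1])
  rows <- lapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    if (any(diff(tr$t_s) <= 0)) stop("timestamps must be strictly increasing")
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    d_acc <- sum(sqrt(dx^2 + dy^2))
    ex <- tr$x_um[nrow(tr)] - tr$x_um[1]
    ey <- tr$y_um[nrow(tr)] - tr$y_um[1]
    d_eu <- sqrt(ex^2 + ey^2)
    x_net <- ex * axis[1] + ey * axis[2]
    y_net <- ex * perp[1] + ey * perp[2]
    flagged <- d_acc == 0
    data.frame(cell_id = tr$cell_id[1], n_steps = nrow(tr) - 1L,
               d_acc = d_acc, d_eu = d_eu, x_net = x_net, y_net = y_net,
               fmi_par = if (flagged) NA_real_ else x_net / d_acc,
               fmi_perp = if (flagged) NA_real_ else y_net / d_acc,
               straightness = if (flagged) NA_real_ else d_eu / d_acc,
               flagged = flagged)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("chemotaxis_metrics", "data.frame")
  res
}

#' Origin-translated trajectories for spider plots
#'
#' Each track is translated so it starts at (0, 0); its endpoint is
#' labelled `"toward"` when the final displacement along the gradient
#' axis is positive, `"away"` otherwise.
#'
#' @param tracks a `cell_tracks` data frame.
#' @param axis gradient axis (see [track_metrics()]).
#' @return A list: `paths` (data frame `cell_id`, `t_s`, `x_um`, `y_um`,
#'   translated) and `endpoints` (`cell_id`, `x_end`, `y_end`, `label`).
#' @export
spider_plot_data <- function(tracks, axis = attr(tracks, "gradient_axis")) {
  if (is.null(axis)) axis <- c(1, 0)
  axis <- axis / sqrt(sum(axis^2))
  if (nrow(tracks) == 0) stop("need at least one track")
  parts <- lapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    tr$x_um <- tr$x_um - tr$x_um[1]
    tr$y_um <- tr$y_um - tr$y_um[1]
    tr
  })
  paths <- do.call(rbind, parts)
  rownames(paths) <- NULL
  endpoints <- do.call(rbind, lapply(parts, function(tr) {
    xe <- tr$x_um[nrow(tr)]; ye <- tr$y_um[nrow(tr)]
    data.frame(cell_id = tr$cell_id[1], x_end = xe, y_end = ye,
               label = if (xe * axis[1] + ye * axis[2] > 0) "toward"
                       else "away")
  }))
  rownames(endpoints) <- NULL
  list(paths = paths, endpoints = endpoints)
}

#' Spider plot of origin-translated tracks
#'
#' Tracks heading along the gradient are drawn black, the rest red, with
#' endpoint dots, matching the conventional presentation of chemotaxis
#' assays.
#'
#' @param x a `cell_tracks` data frame.
#' @param axis gradient axis.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the [spider_plot_data()] used.
#' @export
plot.cell_tracks <- function(x, axis = attr(x, "gradient_axis"), ...) {
  sp <- spider_plot_data(x, axis)
  rng <- range(c(sp$paths$x_um, sp$paths$y_um))
  graphics::plot(NA, xlim = rng, ylim = rng, xlab = "x (um)",
                 ylab = "y (um)", asp = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  for (id in unique(sp$paths$cell_id)) {
    tr <- sp$paths[sp$paths$cell_id == id, ]
    col <- if (sp$endpoints$label[sp$endpoints$cell_id == id] == "toward")
      "black" else "red"
    graphics::lines(tr$x_um, tr$y_um, col = col)
    graphics::points(tr$x_um[nrow(tr)], tr$y_um[nrow(tr)], pch = 16,
                     col = col, cex = 0.6)
  }
  invisible(sp)
}

#' Compare chemotaxis metrics across conditions
#'
#' One-way ANOVA followed by Tukey's multiple comparison test on FMI_par
#' and on straightness across groups. Tracks flagged as stationary or
#' shorter than `min_steps` are excluded (short tracks have wildly
#' variable metrics).
#'
#' @param groups named list of `chemotaxis_metrics` data frames.
#' @param min_steps minimum number of steps per included track.
#' @return A `chemotaxis_comparison` list: per-group summary (`n`,
#'   `mean_fmi_par`, `mean_straightness`), ANOVA p-values and Tukey
#'   tables for both metrics.
#' @export
compare_conditions <- function(groups, min_steps = 10) {
  stopifnot(is.list(groups), length(groups) >= 2)
  long <- do.call(rbind, lapply(names(groups), function(g) {
    m <- groups[[g]]
    m <- m[!m$flagged & m$n_steps >= min_steps, ]
    if (nrow(m) < 3) stop("need >= 3 usable tracks per group (", g, ")")
    data.frame(group = g, fmi_par = m$fmi_par,
               straightness = m$straightness)
  }))
  long$group <- factor(long$group)
  per <- do.call(rbind, lapply(split(long, long$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               mean_fmi_par = mean(d$fmi_par),
               mean_straightness = mean(d$straightness))))
  rownames(per) <- NULL
  test_one <- function(col) {
    if (var(long[[col]]) < .Machine$double.eps) {
      warning("degenerate variance in ", col, "; ANOVA not meaningful")
      return(list(p = NA_real_, tukey = NULL))
    }
    av <- aov(stats::reformulate("group", col), data = long)
    list(p = summary(av)[[1]][["Pr(>F)"]][1], tukey = TukeyHSD(av)$group)
  }
  fmi <- test_one("fmi_par")
  str <- test_one("straightness")
  structure(list(groups = per, anova_p_fmi = fmi$p, tukey_fmi = fmi$tukey,
                 anova_p_straightness = str$p,
                 tukey_straightness = str$tukey),
            class = "chemotaxis_comparison")
}

#' @export
print.chemotaxis_comparison <- function(x, ...) {
  cat("<chemotaxis_comparison>\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("  ANOVA p: FMI_par = %.4g, straightness = %.4g\n",
              x$anova_p_fmi, x$anova_p_straightness))
  invisible(x)
}
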
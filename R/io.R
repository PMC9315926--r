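#' Read and write the package's CSV interchange formats
#'
#' All coordinates follow one convention: 0-based pixel indices, `x` is
#' the column (fast) axis, positions are PSF centres.
#'
#' @param trajs a `trajectories` data frame.
#' @param path file path.
#' @name nanodyn-io
NULL

#' @rdname nanodyn-io
#' @export
write_trajectories_csv <- function(trajs, path) {
  write.csv(as.data.frame(trajs), path, row.names = FALSE)
  meta <- list(pixel_size = attr(trajs, "pixel_size"),
               frame_interval = attr(trajs, "frame_interval"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname nanodyn-io
#' @export
read_trajectories_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "pixel_size") <- meta$pixel_size
    attr(df, "frame_interval") <- meta$frame_interval
  }
  class(df) <- c("trajectories", "data.frame")
  df
}

#' Read/write cell tracks (cell_id, t_s, x_um, y_um)
#'
#' Compatible with manual-tracking exports; an `axis_x`/`axis_y` pair of
#' columns, when present, carries the gradient axis so data recorded in
#' other orientations are rotated rather than re-coded.
#'
#' @param tracks a `cell_tracks` data frame.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- as.data.frame(tracks)
  axis <- attr(tracks, "gradient_axis")
  if (!is.null(axis)) {
    df$axis_x <- axis[1]
    df$axis_y <- axis[2]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  axis <- c(1, 0)
  if (all(c("axis_x", "axis_y") %in% names(df))) {
    axis <- c(df$axis_x[1], df$axis_y[1])
    df$axis_x <- df$axis_y <- NULL
  }
  attr(df, "gradient_axis") <- axis
  class(df) <- c("cell_tracks", "data.frame")
  df
}

#' Read/write a lipid feature table with its species metadata
#'
#' The intensity matrix goes to `path`; ion-mode assignments and internal
#' standard column names go to a sidecar `<path>.species.csv`.
#'
#' @param table a `lipid_table`.
#' @param path file path for the main table.
#' @export
write_lipid_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  ion <- attr(table, "ion_mode")
  is_cols <- attr(table, "is_cols")
  meta <- data.frame(species = names(ion), ion_mode = unname(ion),
                     is_col = unname(is_cols[ion]))
  write.csv(meta, paste0(path, ".species.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_lipid_csv
#' @export
read_lipid_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- read.csv(paste0(path, ".species.csv"))
  ion <- setNames(meta$ion_mode, meta$species)
  modes <- unique(meta[c("ion_mode", "is_col")])
  attr(df, "ion_mode") <- ion
  attr(df, "is_cols") <- setNames(modes$is_col, modes$ion_mode)
  class(df) <- c("lipid_table", "data.frame")
  df
}
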
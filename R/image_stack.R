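#' Image stack container
#'
#' Time-ordered 2D frames with physical calibration. Frames are stored as an
#' H x W x T numeric array; rows are image lines (y), columns the fast scan
#' axis (x). `x` is the column axis and coordinates are 0-based pixel
#' indices throughout the package.
#'
#' @param frames numeric H x W x T array (a single matrix is promoted to
#'   T = 1).
#' @param pixel_size pixel size in micrometres.
#' @param frame_interval time between frames in seconds.
#' @param dwell_time per-pixel dwell time in seconds (raster scans), or `NA`
#'   for camera acquisitions.
#' @param line_time time between scan line starts in seconds, or `NA`.
#' @param bit_depth nominal camera bit depth used for saturation checks.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = NA_real_,
                        dwell_time = NA_real_, line_time = NA_real_,
                        bit_depth = 16L) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (any(frames < 0)) stop("intensities must be >= 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, dwell_time = dwell_time,
                 line_time = line_time, bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.4g um/px)\n",
              d[3], d[1], d[2], x$pixel_size))
  if (!is.na(x$frame_interval))
    cat(sprintf("  frame interval: %g s\n", x$frame_interval))
  if (!is.na(x$dwell_time))
    cat(sprintf("  raster: dwell %g s, line %g s\n", x$dwell_time, x$line_time))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack an `image_stack`.
#' @param i frame index (1-based).
#' @return Numeric H x W matrix.
#' @export
get_frame <- function(stack, i) stack$frames[, , i]

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Intensities are scaled into the 16-bit range; the scale factor is
#' returned invisibly so quantitative values can be restored on read.
#'
#' @param stack an `image_stack`.
#' @param path output file.
#' @param scale scaling to apply before quantization; default scales the
#'   stack maximum to 90% of full range.
#' @return Invisibly, the scale factor used.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  mx <- max(stack$frames)
  if (is.null(scale)) scale <- if (mx > 0) 0.9 * 65535 / mx else 1
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    m <- stack$frames[, , i] * scale / 65535
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file.
#' @param pixel_size,frame_interval physical calibration (not stored in
#'   plain TIFFs, so supplied by the caller).
#' @param scale intensity scale factor to undo (see [write_stack_tiff()]).
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval = NA_real_,
                            scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * 65535 / scale
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}
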
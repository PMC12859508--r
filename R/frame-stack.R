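#' A time-ordered stack of single-channel frames
#'
#' The in-memory container for a microscopy video: a list of identically
#' shaped numeric matrices plus the physical pixel size (um/px), bit
#' depth, optional timestamps and provenance. Pixel coordinates
#' throughout the package are 0-based `(x, y) = (column, row)` with pixel
#' centers at integer coordinates.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param pixel_size um per pixel (> 0); may be NA for stacks read from
#'   plain TIFFs, in which case analysis refuses to run until it is set.
#' @param bit_depth 8 or 16.
#' @param timestamps optional numeric vector of frame times, seconds.
#' @param source optional source path.
#' @param name experiment / video name.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size = NA_real_, bit_depth = 8,
                        timestamps = NULL, source = NA_character_,
                        name = "video") {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape")
  }
  if (!is.na(pixel_size) && pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth), timestamps = timestamps,
                 source = source, name = name),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack '%s': %d frames of %dx%d, %d-bit, pixel %s um\n",
              x$name, length(x$frames), d[1], d[2], x$bit_depth,
              format(x$pixel_size)))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)
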
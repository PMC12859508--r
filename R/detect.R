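#' Detection and boundary parameters for one experiment
#'
#' The tunable imaging parameters: approximate object diameters
#' (`min_size`, `max_size`, pixels) which set the difference-of-Gaussians
#' filter widths, the minimum object intensity as a fraction of the frame
#' maximum, the flood-fill threshold relative to the object's local peak
#' (so uneven background between cells is tolerated), the boundary
#' smoothing width (kept close to 1.0 unless the images are noisy), the
#' tracking match radius (15 px) and tracking memory (10 frames).
#'
#' @param min_intensity minimum intensity, fraction of frame max (0, 1].
#' @param min_size,max_size approximate object diameters, pixels.
#' @param fill_threshold flood-fill intensity fraction of the local peak.
#' @param smoothing_width Gaussian blur sd for boundary detection, pixels.
#' @param track_distance tracker match radius, pixels.
#' @param track_memory tracker memory, frames.
#' @param boundary_mode "condensate" (gradient) or "vesicle" (intensity).
#' @param continuity_max_step max adjacent-ray radius jump, pixels.
#' @param q_max highest Fourier mode used in fitting.
#' @return an object of class `imaging_config`.
#' @export
imaging_config <- function(min_intensity = 0.3, min_size = 15, max_size = 45,
                           fill_threshold = 0.5, smoothing_width = 1.0,
                           track_distance = 15, track_memory = 10,
                           boundary_mode = c("condensate", "vesicle"),
                           continuity_max_step = 3, q_max = 15) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(min_size > 0, max_size > min_size,
            min_intensity > 0, min_intensity <= 1,
            fill_threshold > 0, fill_threshold < 1,
            smoothing_width >= 0, track_distance > 0, track_memory >= 0,
            continuity_max_step > 0, q_max >= 2)
  structure(list(min_intensity = min_intensity, min_size = min_size,
                 max_size = max_size, fill_threshold = fill_threshold,
                 smoothing_width = smoothing_width,
                 track_distance = track_distance,
                 track_memory = as.integer(track_memory),
                 boundary_mode = boundary_mode,
                 continuity_max_step = continuity_max_step,
                 q_max = as.integer(q_max)),
            class = "imaging_config")
}

#' Detect object centers in one frame by difference of Gaussians
#'
#' Band-pass filters the frame with two Gaussians whose widths derive
#' from the configured object diameters (sd = size / (2 sqrt 2)), then
#' keeps 3x3 local maxima of the positive DoG response whose original
#' intensity is at least `min_intensity` times the frame maximum.
#' Returned in descending response order.
#'
#' @param frame numeric matrix.
#' @param config an [imaging_config()].
#' @return data.frame with columns x, y (0-based pixel coords), response,
#'   intensity; zero rows for a blank frame.
#' @export
detect_centers <- function(frame, config) {
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      response = numeric(0), intensity = numeric(0))
  fmax <- max(frame)
  if (fmax <= 0) return(empty)
  s1 <- config$min_size / (2 * sqrt(2))
  s2 <- config$max_size / (2 * sqrt(2))
  dog <- cpp_gaussian_blur(frame, s1) - cpp_gaussian_blur(frame, s2)
  nr <- nrow(dog); nc <- ncol(dog)
  if (nr < 3 || nc < 3) return(empty)
  core <- dog[2:(nr - 1), 2:(nc - 1)]
  ismax <- core > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & (core >= dog[2:(nr - 1) + dy, 2:(nc - 1) + dx])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ys <- idx[, 1]     # 0-based row of the maximum (core offset +1 -1)
  xs <- idx[, 2]
  inten <- frame[cbind(ys + 1, xs + 1)]
  keep <- inten >= config$min_intensity * fmax
  if (!any(keep)) return(empty)
  res <- core[idx][keep]
  out <- data.frame(x = xs[keep], y = ys[keep], response = res,
                    intensity = inten[keep])
  out <- out[order(-out$response), , drop = FALSE]
  # non-maximum suppression: a plateau or noisy peak yields clustered
  # maxima; keep only the strongest within min_size of each other
  keep_i <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (!length(keep_i) ||
        all((out$x[i] - out$x[keep_i])^2 + (out$y[i] - out$y[keep_i])^2 >=
              config$min_size^2)) {
      keep_i <- c(keep_i, i)
    }
  }
  out <- out[keep_i, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate an object's extent by flood fill
#'
#' Region-grows 4-connectedly from the detected center over pixels at or
#' above `fill_threshold` times the object's local peak intensity (the
#' maximum within `min_size/2` pixels of the center), and pads the mask's
#' bounding rectangle by `max(5, 3 * smoothing_width)` pixels so the tanh
#' interface is fully enclosed.
#'
#' @param frame numeric matrix.
#' @param center c(x, y), 0-based.
#' @param config an [imaging_config()].
#' @return a `detection`: list with `center`, `centroid` (mask centroid),
#'   `mask` (logical matrix, frame-sized), `bbox` (c(x0, y0, x1, y1),
#'   0-based inclusive, clipped to the frame), `peak`, `area`; or NULL
#'   when the seed lies below the fill threshold (degenerate extent).
#' @export
estimate_extent <- function(frame, center, config) {
  nr <- nrow(frame); nc <- ncol(frame)
  x <- round(center[1]); y <- round(center[2])
  rad <- max(1, floor(config$min_size / 2))
  xs <- max(0, x - rad):min(nc - 1, x + rad)
  ys <- max(0, y - rad):min(nr - 1, y + rad)
  peak <- max(frame[ys + 1, xs + 1])
  # a seed whose neighborhood never reaches the detection intensity is
  # background: flood-filling from it would run away over the frame
  if (peak < config$min_intensity * max(frame)) return(NULL)
  thresh <- config$fill_threshold * peak
  if (frame[y + 1, x + 1] < thresh) return(NULL)
  mask <- cpp_flood_fill(frame, x, y, thresh)
  idx <- which(mask, arr.ind = TRUE)
  pad <- max(5, 3 * config$smoothing_width)
  x0 <- max(0, min(idx[, 2]) - 1 - pad)
  x1 <- min(nc - 1, max(idx[, 2]) - 1 + pad)
  y0 <- max(0, min(idx[, 1]) - 1 - pad)
  y1 <- min(nr - 1, max(idx[, 1]) - 1 + pad)
  structure(list(center = center,
                 centroid = c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1),
                 mask = mask, bbox = c(x0, y0, x1, y1), peak = peak,
                 area = nrow(idx)),
            class = "detection")
}
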
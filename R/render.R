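#' Render a droplet contour as a confocal-like image
#'
#' Paints the tanh interface profile
#' \eqn{I(d) = \mathrm{bg} + A(1/2 - 1/2\,\tanh((d - r(\phi))/\zeta))}
#' where `d` is the radial distance of a pixel from the object center and
#' `r(phi)` the contour radius at that pixel's polar angle, then adds
#' Gaussian noise of sd `noise_sd * A` and clips/quantizes to the bit
#' depth. Intensities are integer levels in `[0, 2^bit_depth - 1]`.
#'
#' @param contour a `contour_curve` with radii in pixels.
#' @param params a [simulation_params()] object (zeta, amplitude,
#'   background, noise_sd, bit_depth).
#' @param frame_shape integer c(n_rows, n_cols) in pixels.
#' @param center c(x, y) pixel coordinates of the object center (0-based).
#' @param seed integer seed for the noise stream.
#' @return numeric matrix of quantized intensity levels.
#' @export
render_frame <- function(contour, params, frame_shape, center, seed = 1) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  rmax <- max(contour$radii)
  if (center[1] - rmax < 5 || center[2] - rmax < 5 ||
      center[1] + rmax > nc - 1 - 5 || center[2] + rmax > nr - 1 - 5) {
    stop("contour does not fit inside the frame with a 5-pixel margin")
  }
  levels_max <- 2^params$bit_depth - 1
  A <- params$amplitude * levels_max
  bg <- params$background * levels_max
  img <- cpp_render_tanh(nr, nc, center[1], center[2], contour$radii,
                         params$zeta, A, bg)
  if (params$noise_sd > 0) {
    img <- img + with_seed(seed,
      matrix(rnorm(nr * nc, sd = params$noise_sd * A), nr, nc))
  }
  matrix(pmin(pmax(round(img), 0), levels_max), nr, nc)
}

#' Generate a synthetic fluctuation video with ground truth
#'
#' Builds a stack of `n_frames` frames containing `n_objects` fluctuating
#' droplets at fixed centers. Each frame is an independent equilibrium
#' sample of every droplet's shape (no relaxation dynamics are modeled:
#' the spectrum averaging only requires equilibrium statistics, so
#' frame-rate effects cannot be emulated). Droplet centers are laid out
#' on a grid with enough margin that objects never overlap.
#'
#' @param params a [simulation_params()] object; `radius`/`pixel_size`
#'   set the droplet radius in pixels.
#' @param n_frames number of frames (>= 1).
#' @param n_objects number of droplets (>= 0).
#' @param seed integer seed; the whole stack is reproducible from it.
#' @param frame_shape optional c(n_rows, n_cols); default sized to fit.
#' @param centers optional n_objects x 2 matrix of (x, y) centers
#'   (0-based pixels); defaults to a non-overlapping grid. Centers
#'   closer than two radii plus a 10-px margin are rejected.
#' @return a list with `stack` (a `frame_stack`) and `truth`
#'   (data.frame: object, sigma, kappa, radius_um, radius_px, cx, cy).
#' @export
generate_video <- function(params, n_frames, n_objects, seed = 1,
                           frame_shape = NULL, centers = NULL) {
  stopifnot(n_frames >= 1, n_objects >= 0)
  r_px <- params$radius / params$pixel_size
  cell <- ceiling(2 * r_px + 24)          # per-object tile incl. margins
  n_cols_obj <- max(1, ceiling(sqrt(max(1, n_objects))))
  n_rows_obj <- max(1, ceiling(max(1, n_objects) / n_cols_obj))
  if (is.null(frame_shape)) {
    frame_shape <- c(n_rows_obj * cell, n_cols_obj * cell)
  }
  if (n_objects > 0) {
    if (is.null(centers)) {
      idx <- seq_len(n_objects) - 1
      centers <- cbind(x = (idx %% n_cols_obj) * cell + cell / 2,
                       y = (idx %/% n_cols_obj) * cell + cell / 2)
    } else {
      centers <- matrix(centers, ncol = 2)
      stopifnot(nrow(centers) == n_objects)
    }
    dmin <- if (n_objects > 1) min(dist(centers)) else Inf
    if (dmin < 2 * r_px + 10) stop("objects would overlap")
  } else {
    centers <- NULL
  }
  frames <- vector("list", n_frames)
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_frames * (n_objects + 1)))
  levels_max <- 2^params$bit_depth - 1
  bg <- params$background * levels_max
  A <- params$amplitude * levels_max
  k <- 0
  for (f in seq_len(n_frames)) {
    img <- matrix(bg, frame_shape[1], frame_shape[2])
    if (n_objects > 0) {
      for (o in seq_len(n_objects)) {
        k <- k + 1
        sh <- sample_shape(params, seeds[k])
        ct <- cross_section_contour(sh, params$plane_offset)
        ct$radii <- ct$radii / params$pixel_size   # um -> px
        img <- img + cpp_render_tanh(frame_shape[1], frame_shape[2],
                                     centers[o, 1], centers[o, 2],
                                     ct$radii, params$zeta, A, 0)
      }
    }
    k <- k + 1
    if (params$noise_sd > 0) {
      img <- img + with_seed(seeds[k],
        matrix(rnorm(length(img), sd = params$noise_sd * A),
               frame_shape[1], frame_shape[2]))
    }
    frames[[f]] <- matrix(pmin(pmax(round(img), 0), levels_max),
                          frame_shape[1], frame_shape[2])
  }
  truth <- if (n_objects > 0) {
    data.frame(object = seq_len(n_objects) - 1L, sigma = params$sigma,
               kappa = params$kappa, radius_um = params$radius,
               radius_px = r_px, cx = centers[, 1], cy = centers[, 2])
  } else {
    data.frame(object = integer(0), sigma = numeric(0), kappa = numeric(0),
               radius_um = numeric(0), radius_px = numeric(0),
               cx = numeric(0), cy = numeric(0))
  }
  stack <- frame_stack(frames, pixel_size = params$pixel_size,
                       bit_depth = params$bit_depth, name = "synthetic")
  list(stack = stack, truth = truth)
}
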
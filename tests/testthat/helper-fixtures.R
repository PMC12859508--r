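# Shared fixtures, built in code at test time.

kB <- flickerspec:::.kB

# simulation_params with a given reduced tension (kappa in kBT, R in um)
params_for_sigma_bar <- function(sigma_bar, kappa = 5, radius = 2,
                                 temperature = 298, ...) {
  sigma <- sigma_bar * kappa * kB * temperature / (radius * 1e-6)^2
  simulation_params(sigma = sigma, kappa = kappa, radius = radius,
                    temperature = temperature, ...)
}

# a perfect-circle contour_curve in pixels
circle_contour <- function(radius, n = 400) {
  structure(list(angles = 2 * pi * seq(0, n - 1) / n,
                 radii = rep(radius, n), center = c(0, 0), valid = TRUE),
            class = "contour_curve")
}

contour_from_radii <- function(radii) {
  n <- length(radii)
  structure(list(angles = 2 * pi * seq(0, n - 1) / n, radii = radii,
                 center = c(0, 0), valid = TRUE),
            class = "contour_curve")
}

# noiseless rendered disk and its extraction config
render_disk <- function(radius_px, frame = 64, zeta = 0.8, noise_sd = 0,
                        bit_depth = 8, seed = 1) {
  p <- simulation_params(radius = radius_px * 0.1, pixel_size = 0.1,
                         zeta = zeta, noise_sd = noise_sd,
                         bit_depth = bit_depth)
  render_frame(circle_contour(radius_px), p, c(frame, frame),
               c(frame / 2, frame / 2), seed = seed)
}

# full single-object boundary extraction from an image
extract_contour <- function(img, config = imaging_config(min_size = 20,
                                                         max_size = 45)) {
  det <- detect_centers(img, config)
  ext <- estimate_extent(img, c(det$x[1], det$y[1]), config)
  bb <- ext$bbox
  sub <- img[(bb[2]:bb[4]) + 1, (bb[1]:bb[3]) + 1, drop = FALSE]
  fld <- build_field(sub, ext$centroid - bb[1:2], config$smoothing_width,
                     config$boundary_mode)
  ct <- trace_boundary(fld)
  ct$center <- ct$center + bb[1:2]
  ct
}

# an aggregate-style record row for the population filters
make_record <- function(sigma = 1e-6, continuity = 0.9, epsilon = 0.1,
                        delta_epsilon = 0.2, n_frames = 500) {
  data.frame(sigma = sigma, continuity = continuity, epsilon = epsilon,
             delta_epsilon = delta_epsilon, n_frames = n_frames)
}
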
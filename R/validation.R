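#' Simulate an accumulated spectrum record without rendering
#'
#' Draws `n_shapes` independent equilibrium droplet shapes, takes the
#' planar cross-section of each, recenters and normalizes the contours
#' exactly as the image pipeline does, and accumulates the Fourier modes
#' into a `spectrum_record`. This is the contour-level (no rendering, no
#' detection noise) path used for parameter-recovery studies; it shares
#' all analysis code with the image path from recentering onward.
#'
#' @param params a [simulation_params()].
#' @param n_shapes number of independent equilibrium shapes (frames).
#' @param plane_offset imaging-plane offset, fraction of R (default:
#'   from `params`).
#' @param seed RNG seed.
#' @param q_max highest mode (default 15).
#' @param n_angles contour sampling (default 400).
#' @return a `spectrum_record` (mean radius in um).
#' @export
simulate_spectrum_record <- function(params, n_shapes, plane_offset = NULL,
                                     seed = 1, q_max = 15, n_angles = 400) {
  rt <- simulate_contour_batch(params, n_shapes, plane_offset,
                               n_angles, seed)   # units of R
  rc <- cpp_recenter(rt, 20L, 1e-12)
  r <- rc$radii
  rbar <- colMeans(r)
  V <- mvfft(r / matrix(rbar, n_angles, n_shapes, byrow = TRUE)) / n_angles
  V <- V[seq_len(q_max + 1), , drop = FALSE]
  sq <- Mod(V)^2
  mean_sq <- rowMeans(sq)
  mean_V <- rowMeans(V)
  rbar_R <- mean(rbar)
  rec <- structure(list(mean_sq = mean_sq, mean_V = mean_V,
                        se_sq = apply(sq, 1, sd) / sqrt(n_shapes),
                        q_max = as.integer(q_max), n_frames = n_shapes,
                        continuity = 1,
                        mean_radius_px = rbar_R * params$radius /
                          params$pixel_size,
                        mean_radius_um = rbar_R * params$radius),
                   class = "spectrum_record")
  rec$F_sq <- shape_correct(rec)
  rec
}

#' Off-equator parameter-recovery study
#'
#' For each of `n_droplets` ground-truth parameter sets (reduced tension
#' drawn log-uniformly over `sigma_bar_range`, fixed rigidity and
#' radius), simulates `n_shapes` equilibrium shapes, cross-sections them
#' at `plane_offset` radii from the equator, computes the corrected mode
#' spectrum for q = 2..`q_max` and fits the equatorial theoretical
#' spectrum — quantifying the bias incurred by imaging away from the
#' equator (the fit uses the measured cut radius, as an experiment
#' would).
#'
#' @param n_droplets number of droplets (default 20).
#' @param n_shapes equilibrium samples per droplet (default 1000).
#' @param plane_offset fraction of R (default 0.34).
#' @param sigma_bar_range reduced-tension span (default c(10, 1000)).
#' @param kappa rigidity, kB*T (default 5).
#' @param radius droplet radius, um (default 2).
#' @param temperature K (default 298).
#' @param seed master seed.
#' @param q_max,l_max fitting controls.
#' @return data.frame with one row per droplet: sigma_bar_true,
#'   sigma_true, kappa_true, sigma_fit, kappa_fit, rel_err_sigma,
#'   rel_err_kappa.
#' @export
recover_parameters_offequator <- function(n_droplets = 20, n_shapes = 1000,
                                          plane_offset = 0.34,
                                          sigma_bar_range = c(10, 1000),
                                          kappa = 5, radius = 2,
                                          temperature = 298, seed = 1,
                                          q_max = 15, l_max = 75) {
  kB_T <- .kB * temperature
  sbs <- with_seed(seed, 10^runif(n_droplets, log10(sigma_bar_range[1]),
                                  log10(sigma_bar_range[2])))
  rows <- lapply(seq_len(n_droplets), function(i) {
    sigma <- sbs[i] * kappa * kB_T / (radius * 1e-6)^2
    params <- simulation_params(sigma = sigma, kappa = kappa,
                                radius = radius,
                                temperature = temperature, l_max = l_max)
    rec <- simulate_spectrum_record(params, n_shapes, plane_offset,
                                    seed = seed + i, q_max = q_max)
    fit <- fit_spectrum(rec, temperature, q_range = 2:q_max, l_max = l_max)
    data.frame(sigma_bar_true = sbs[i], sigma_true = sigma,
               kappa_true = kappa, sigma_fit = fit$sigma,
               kappa_fit = fit$kappa,
               rel_err_sigma = abs(fit$sigma - sigma) / sigma,
               rel_err_kappa = abs(fit$kappa - kappa) / kappa)
  })
  do.call(rbind, rows)
}
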
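#' Ground-truth parameters for the synthetic fluctuating-droplet generator
#'
#' Bundles the physical and imaging parameters that define a simulated
#' quasi-spherical droplet: interfacial tension `sigma` (N/m), bending
#' rigidity `kappa` (units of kB*T), mean radius (um), temperature (K),
#' spherical-harmonic cutoff `l_max`, interface width `zeta` (pixels),
#' pixel size (um/px), rendering amplitude/background (fractions of the
#' full intensity scale), additive noise level, bit depth, and the
#' imaging-plane offset as a fraction of the radius.
#'
#' @param sigma interfacial tension, N/m (>= 0).
#' @param kappa bending rigidity in units of kB*T (> 0).
#' @param radius mean droplet radius, um (> 0).
#' @param temperature absolute temperature, K. The default 298 K is a
#'   package choice; the physical scale of the fluctuations is set by
#'   kB*T so this must reflect the experiment.
#' @param l_max spherical-harmonic cutoff (integer >= 2). 75 is
#'   sufficient for the mode sum to converge.
#' @param zeta interface width of the tanh intensity profile, pixels.
#' @param pixel_size um per pixel.
#' @param amplitude peak intensity of a droplet as a fraction of the
#'   full scale (default 200/255).
#' @param background background intensity as a fraction of full scale.
#' @param noise_sd additive Gaussian noise sd as a fraction of `amplitude`.
#' @param bit_depth 8 or 16.
#' @param plane_offset imaging-plane offset as a fraction of the radius,
#'   in (-1, 1); 0 is the equator.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(sigma = 1.5e-6, kappa = 5, radius = 2,
                              temperature = 298, l_max = 75, zeta = 0.8,
                              pixel_size = 0.1, amplitude = 200 / 255,
                              background = 10 / 255, noise_sd = 0.02,
                              bit_depth = 8, plane_offset = 0) {
  stopifnot(sigma >= 0, kappa > 0, radius > 0, temperature > 0,
            zeta > 0, pixel_size > 0, noise_sd >= 0,
            bit_depth %in% c(8L, 16L), abs(plane_offset) < 1)
  l_max <- as.integer(l_max)
  if (l_max < 2) stop("l_max must be >= 2")
  structure(list(sigma = sigma, kappa = kappa, radius = radius,
                 temperature = temperature, l_max = l_max, zeta = zeta,
                 pixel_size = pixel_size, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth),
                 plane_offset = plane_offset),
            class = "simulation_params")
}

#' Reduced tension of a parameter set
#'
#' The dimensionless combination \eqn{\bar\sigma = \sigma R^2 / \kappa}
#' (with \eqn{\kappa} converted to Joules via kB*T) that controls the
#' crossover between tension- and bending-dominated fluctuation modes.
#'
#' @param params a [simulation_params()] object.
#' @return numeric scalar.
#' @export
reduced_tension <- function(params) {
  kappa_J <- params$kappa * .kB * params$temperature
  params$sigma * (params$radius * 1e-6)^2 / kappa_J
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("simulation_params:\n")
  cat(sprintf("  sigma   %.4g N/m   kappa %.4g kBT   R %.4g um   T %g K\n",
              x$sigma, x$kappa, x$radius, x$temperature))
  cat(sprintf("  sigma_bar %.4g   l_max %d   zeta %g px   pixel %g um\n",
              reduced_tension(x), x$l_max, x$zeta, x$pixel_size))
  cat(sprintf("  render: A %.3g bg %.3g noise %.3g bit %d offset %g\n",
              x$amplitude, x$background, x$noise_sd, x$bit_depth,
              x$plane_offset))
  invisible(x)
}
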
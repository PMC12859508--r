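# Per-degree variance of the surface modes: <|u_lm|^2> =
# kB*T / (kappa_J * (l+2)(l-1)(l(l+1) + sigma_bar)), independent of m.
# With kappa expressed in kB*T units the prefactor is 1/kappa.
mode_variance <- function(l, kappa_kbt, sigma_bar) {
  1 / (kappa_kbt * (l + 2) * (l - 1) * (l * (l + 1) + sigma_bar))
}

#' Draw one equilibrium droplet shape
#'
#' Samples spherical-harmonic surface amplitudes \eqn{u_{lm}} (degrees
#' \eqn{2 \le l \le l_{max}}) from the equilibrium distribution implied by
#' the Helfrich-plus-tension energy: each mode is Gaussian with
#' \eqn{\langle|u_{lm}|^2\rangle = k_B T / [\kappa (l+2)(l-1)(l(l+1)+\bar\sigma)]}.
#' Coefficients are stored for \eqn{m \ge 0}; \eqn{m < 0} follows from the
#' reality constraint \eqn{u_{l,-m} = (-1)^m \bar u_{lm}}. The monopole
#' (volume) and dipole (translation) degrees are absent, matching their
#' removal by normalization and recentering in the analysis.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed fixing the random stream.
#' @return an object of class `harmonic_shape`: list with `amplitudes`
#'   (complex matrix indexed `[l+1, m+1]`, rows 3..l_max+1 populated),
#'   `radius` (um) and `l_max`.
#' @export
sample_shape <- function(params, seed) {
  stopifnot(inherits(params, "simulation_params"))
  l_max <- params$l_max
  sigma_bar <- reduced_tension(params)
  amp <- matrix(0 + 0i, l_max + 1, l_max + 1)
  with_seed(seed, {
    for (l in 2:l_max) {
      v <- mode_variance(l, params$kappa, sigma_bar)
      # m = 0: real Gaussian with variance v
      amp[l + 1, 1] <- rnorm(1, sd = sqrt(v))
      # m > 0: complex Gaussian, total variance v (v/2 per quadrature)
      m <- seq_len(l)
      amp[l + 1, m + 1] <- complex(real = rnorm(l, sd = sqrt(v / 2)),
                                   imaginary = rnorm(l, sd = sqrt(v / 2)))
    }
  })
  structure(list(amplitudes = amp, radius = params$radius, l_max = l_max),
            class = "harmonic_shape")
}

#' Look up a surface amplitude, applying the reality constraint
#'
#' @param shape a [sample_shape()] result.
#' @param l degree.
#' @param m order, may be negative.
#' @return complex scalar \eqn{u_{lm}}.
#' @export
shape_amplitude <- function(shape, l, m) {
  stopifnot(l >= 0, abs(m) <= l)
  if (l > shape$l_max || l < 2) return(0 + 0i)
  if (m >= 0) shape$amplitudes[l + 1, m + 1]
  else (-1)^(-m) * Conj(shape$amplitudes[l + 1, -m + 1])
}

#' Planar cross-section of a fluctuating droplet
#'
#' Cuts the surface \eqn{r(\theta,\phi) = R(1 + \sum u_{lm} Y_{lm})} with a
#' horizontal plane at height `plane_offset * R` (the polar angle of the
#' cut is \eqn{\theta_0 = \arccos(\mathrm{offset})}; the equator is offset
#' 0). The surface is evaluated to first order in the fluctuation
#' amplitudes, consistent with the quadratic energy that generated them.
#' To that order the in-plane radius of the fixed-height cut is
#' \eqn{\rho(\phi) = R(\sin\theta_0 + u(\theta_0,\phi)/\sin\theta_0)}: the
#' radial fluctuation is geometrically amplified by \eqn{1/\sin\theta_0}
#' off the equator (at the equator the expression reduces to
#' \eqn{R(1 + u)}).
#'
#' @param shape a [sample_shape()] result.
#' @param plane_offset fraction of the radius, |offset| < 1.
#' @param n_angles number of equally spaced polar angles (default 400).
#' @return a `contour_curve`: list with `angles`, `radii` (same units as
#'   `shape$radius`), `center` (c(0, 0)) and `valid = TRUE`.
#' @export
cross_section_contour <- function(shape, plane_offset = 0, n_angles = 400) {
  stopifnot(abs(plane_offset) < 1)
  l_max <- shape$l_max
  x0 <- plane_offset            # cos(theta_0)
  s0 <- sqrt(1 - x0^2)          # sin(theta_0): unperturbed in-plane radius / R
  P <- legendre_normalized_table(l_max, x0)
  phi <- 2 * pi * seq(0, n_angles - 1) / n_angles
  # a_m = sum_l u_lm * Pbar_lm(x0); r/R = s0 + Re(a_0 + 2 sum_{m>0} a_m e^{i m phi})
  ls <- 2:l_max
  a <- vapply(0:l_max, function(m) {
    lv <- ls[ls >= max(2, m)]
    if (!length(lv)) return(0 + 0i)
    sum(shape$amplitudes[lv + 1, m + 1] * P[lv + 1, m + 1])
  }, complex(1))
  E <- exp(1i * outer(phi, 0:l_max))      # n_angles x (l_max+1)
  w <- c(1, rep(2, l_max))                # m=0 once, m>0 carry conjugates
  dr <- as.numeric(Re(E %*% (w * a)))
  radii <- shape$radius * (s0 + dr / s0)
  structure(list(angles = phi, radii = radii, center = c(0, 0),
                 valid = TRUE), class = "contour_curve")
}

# Batch path used by the Monte-Carlo oracles and the off-equator
# acceptance run: identical math to sample_shape() + cross_section_contour()
# but vectorized over shapes (verified against the single-shape path in
# the tests). Returns the n_angles x n_shapes matrix of radii in units of
# the mean radius R.
simulate_contour_batch <- function(params, n_shapes, plane_offset = NULL,
                                   n_angles = 400, seed = 1) {
  l_max <- params$l_max
  if (is.null(plane_offset)) plane_offset <- params$plane_offset
  sigma_bar <- reduced_tension(params)
  x0 <- plane_offset
  s0 <- sqrt(1 - x0^2)
  P <- legendre_normalized_table(l_max, x0)
  ls <- 2:l_max
  sdv <- sqrt(mode_variance(ls, params$kappa, sigma_bar))
  A <- matrix(0 + 0i, l_max + 1, n_shapes)   # a_m per shape, rows m = 0..l_max
  with_seed(seed, {
    for (m in 0:l_max) {
      lv <- ls[ls >= max(2, m)]
      if (!length(lv)) next
      nl <- length(lv)
      if (m == 0) {
        G <- matrix(rnorm(nl * n_shapes), nl, n_shapes) * sdv[lv - 1]
      } else {
        G <- (matrix(rnorm(nl * n_shapes), nl, n_shapes) +
                1i * matrix(rnorm(nl * n_shapes), nl, n_shapes)) *
          (sdv[lv - 1] / sqrt(2))
      }
      A[m + 1, ] <- crossprod(P[lv + 1, m + 1], G)
    }
  })
  phi <- 2 * pi * seq(0, n_angles - 1) / n_angles
  E <- exp(1i * outer(phi, 0:l_max))
  w <- c(1, rep(2, l_max))
  s0 + Re(E %*% (w * A)) / s0
}
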
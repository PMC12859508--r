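# Per-mode summation tables for the theoretical spectrum:
# coef[l, q] = (N_lq P_lq(0))^2 / ((l+2)(l-1)) for l = q..l_max (l+q even),
# lam[l] = l(l+1). Cached per (q_range, l_max).
theory_tables <- local({
  cache <- new.env(parent = emptyenv())
  function(q_range, l_max) {
    key <- paste(min(q_range), max(q_range), l_max, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    tabs <- lapply(q_range, function(q) {
      l <- seq(q, l_max)
      l <- l[(l + q) %% 2 == 0 & l >= 2]
      list(coef = equatorial_legendre(l, q)^2 / ((l + 2) * (l - 1)),
           lam = l * (l + 1))
    })
    names(tabs) <- paste0("q", q_range)
    cache[[key]] <- tabs
    tabs
  }
})

#' Theoretical equatorial fluctuation spectrum
#'
#' Evaluates the thermal spectrum of a quasi-spherical interface with
#' tension and bending rigidity,
#' \deqn{\langle|V_q|^2\rangle = \frac{k_B T}{\kappa} \sum_{l=q}^{l_{max}}
#'   \frac{N_{lq}^2 P_{lq}^2(0)}{(l+2)(l-1)[l(l+1)+\bar\sigma]},}
#' with \eqn{\kappa} in kB*T units (so the prefactor is \eqn{1/\kappa})
#' and \eqn{\bar\sigma = \sigma R^2/\kappa} the reduced tension. Only
#' degrees with \eqn{l + q} even contribute (equatorial parity).
#'
#' @param sigma_bar reduced tension (>= 0).
#' @param kappa bending rigidity, kB*T units (> 0).
#' @param q_range integer modes (default 2:15, all >= 2).
#' @param l_max summation cutoff (default 75, sufficient for convergence).
#' @return numeric vector named q2..; dimensionless mode power.
#' @export
theoretical_spectrum <- function(sigma_bar, kappa, q_range = 2:15,
                                 l_max = 75) {
  stopifnot(sigma_bar >= 0, kappa > 0, min(q_range) >= 2)
  if (l_max < max(q_range)) stop("l_max must be >= max(q_range)")
  tabs <- theory_tables(q_range, l_max)
  out <- vapply(tabs, function(tb) sum(tb$coef / (tb$lam + sigma_bar)),
                numeric(1))
  out / kappa
}

# kappa -> 0 limit of the spectrum divided by kB T/(sigma R^2):
# T_q = sum_l (N_lq P_lq(0))^2 / ((l+2)(l-1))
tension_only_shape <- function(q_range = 2:15, l_max = 75) {
  vapply(theory_tables(q_range, l_max), function(tb) sum(tb$coef),
         numeric(1))
}

#' Log-ratio fitting error between two spectra
#'
#' \eqn{\varepsilon = \sum_q [\log_{10}(|F_{q,theo}|^2 /
#' |F_{q,exp}|^2)]^2}; the log ratio makes every mode contribute to the
#' fit even though the spectrum spans orders of magnitude.
#'
#' @param theory,experiment positive spectra on the same modes.
#' @return non-negative scalar.
#' @export
spectral_error <- function(theory, experiment) {
  if (length(theory) != length(experiment)) stop("length mismatch")
  if (any(theory <= 0) || any(experiment <= 0)) {
    stop("spectra must be strictly positive")
  }
  sum(log10(theory / experiment)^2)
}

#' Fit the theoretical spectrum to a corrected experimental spectrum
#'
#' Stage 1 evaluates the fitting error on a log-spaced grid spanning 14
#' decades in both reduced tension (default \eqn{10^{-4}..10^{10}}) and
#' bending rigidity (default \eqn{10^{-3}..10^{11}} kB*T) at
#' `grid_points_per_decade` points per decade; the surface has a single
#' minimum, so stage 2 refines the best grid point by downhill
#' minimization over \eqn{(\log\bar\sigma, \log\kappa)}. Physical
#' tension is recovered as \eqn{\sigma = \bar\sigma\kappa/R^2} using the
#' measured mean radius. Also computes the tension-only comparison
#' \eqn{\Delta\varepsilon} and the Durbin-Watson statistic of the final
#' per-mode log-ratio residuals.
#'
#' @param record a `spectrum_record` with `F_sq` and `mean_radius_um`.
#' @param temperature K.
#' @param q_range modes to fit (default 2:15).
#' @param l_max summation cutoff.
#' @param grid_points_per_decade stage-1 density (default 8).
#' @param sigma_bar_range,kappa_range stage-1 spans (14 decades each).
#' @return a `fit_result`: sigma (N/m), sigma_uNm, kappa (kB*T),
#'   sigma_bar, epsilon, epsilon_sigma_only, delta_epsilon,
#'   durbin_watson, se_log10_sigma_bar, se_log10_kappa, se_sigma,
#'   se_kappa, converged, plus the fitted spectrum.
#' @export
fit_spectrum <- function(record, temperature = 298, q_range = 2:15,
                         l_max = 75, grid_points_per_decade = 8,
                         sigma_bar_range = c(1e-4, 1e10),
                         kappa_range = c(1e-3, 1e11)) {
  F_sq <- record$F_sq[paste0("q", q_range)]
  if (any(!is.finite(F_sq)) || any(F_sq <= 0)) {
    stop("corrected spectrum must be positive on the fitted modes")
  }
  R_um <- record$mean_radius_um
  tabs <- theory_tables(q_range, l_max)
  logF <- log10(F_sq)
  nq <- length(q_range)

  # stage 1: grid across 14 decades in each parameter
  n1 <- round(log10(sigma_bar_range[2] / sigma_bar_range[1]) *
                grid_points_per_decade) + 1
  n2 <- round(log10(kappa_range[2] / kappa_range[1]) *
                grid_points_per_decade) + 1
  lsb <- seq(log10(sigma_bar_range[1]), log10(sigma_bar_range[2]),
             length.out = n1)
  lkp <- seq(log10(kappa_range[1]), log10(kappa_range[2]),
             length.out = n2)
  # log10 S_q(sigma_bar) on the grid (kappa enters additively in log space)
  S <- vapply(tabs, function(tb) {
    vapply(10^lsb, function(sb) sum(tb$coef / (tb$lam + sb)), numeric(1))
  }, numeric(n1))                      # n1 x nq
  M <- log10(S) - matrix(logF, n1, nq, byrow = TRUE)
  rs <- rowSums(M)
  rs2 <- rowSums(M^2)
  eps_grid <- outer(rs2, rep(1, n2)) - 2 * outer(rs, lkp) +
    nq * outer(rep(1, n1), lkp^2)
  best <- arrayInd(which.min(eps_grid), dim(eps_grid))
  start <- c(lsb[best[1]], lkp[best[2]])
  eps_start <- eps_grid[best[1], best[2]]

  obj <- function(p) {
    th <- theoretical_spectrum(10^p[1], 10^p[2], q_range, l_max)
    sum((log10(th) - logF)^2)
  }
  opt <- tryCatch(optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0
  if (is.null(opt) || opt$value > eps_start) {
    opt <- list(par = start, value = eps_start)
  }
  sigma_bar <- 10^opt$par[1]
  kappa <- 10^opt$par[2]
  eps <- opt$value

  kappa_J <- kappa * .kB * temperature
  sigma <- if (is.na(R_um)) NA_real_ else
    sigma_bar * kappa_J / (R_um * 1e-6)^2

  # linearized standard errors from the final Jacobian of the residuals
  th0 <- theoretical_spectrum(sigma_bar, kappa, q_range, l_max)
  res <- log10(th0) - logF
  h <- 1e-5
  ths <- theoretical_spectrum(10^(opt$par[1] + h), kappa, q_range, l_max)
  J1 <- (log10(ths) - log10(th0)) / h
  J2 <- rep(1, nq)                     # d log10(S/kappa) / d log10 kappa = -1
  J <- cbind(J1, -J2)
  se_log <- tryCatch({
    s2 <- eps / max(nq - 2, 1)
    sqrt(diag(s2 * solve(crossprod(J))))
  }, error = function(e) c(NA_real_, NA_real_))

  tension <- fit_tension_only_impl(logF, q_range, l_max)
  delta_eps <- abs(eps - tension$epsilon)
  dw <- durbin_watson(res)

  structure(list(
    sigma = sigma, sigma_uNm = sigma * 1e6, kappa = kappa,
    sigma_bar = sigma_bar, epsilon = eps,
    epsilon_sigma_only = tension$epsilon, delta_epsilon = delta_eps,
    durbin_watson = dw,
    se_log10_sigma_bar = se_log[1], se_log10_kappa = se_log[2],
    se_sigma = sigma * log(10) * sqrt(sum(se_log^2)),
    se_kappa = kappa * log(10) * se_log[2],
    converged = converged, fitted = th0, residuals = res,
    q_range = q_range, mean_radius_um = R_um,
    temperature = temperature), class = "fit_result")
}

# one-parameter tension-only fit; the log-amplitude has a closed-form
# optimum because the model is a pure vertical shift in log space
fit_tension_only_impl <- function(logF, q_range, l_max) {
  logT <- log10(tension_only_shape(q_range, l_max))
  shift <- mean(logF - logT)           # log10 of kB T/(sigma R^2)
  eps <- sum((logT + shift - logF)^2)
  list(epsilon = eps, log10_amplitude = shift)
}

#' Tension-only model comparison
#'
#' Fits the one-parameter \eqn{\kappa \to 0} limit of the spectrum,
#' \eqn{\langle|V_q|^2\rangle = \frac{k_B T}{\sigma R^2} \sum_l
#' \frac{N_{lq}^2 P_{lq}^2(0)}{(l+2)(l-1)},} and returns its minimal
#' error and \eqn{\Delta\varepsilon = |\varepsilon(\sigma,\kappa) -
#' \varepsilon(\sigma)|}. A small \eqn{\Delta\varepsilon} means bending
#' rigidity is not identifiable from the spectrum (the population filter
#' requires \eqn{\Delta\varepsilon > 0.03}).
#'
#' @param record a `spectrum_record`.
#' @param temperature K.
#' @param q_range,l_max as in [fit_spectrum()].
#' @param fit optional existing [fit_spectrum()] result to reuse.
#' @return list with `epsilon_sigma_only`, `delta_epsilon`, `sigma`
#'   (N/m, from the one-parameter fit when the radius is known).
#' @export
fit_tension_only <- function(record, temperature = 298, q_range = 2:15,
                             l_max = 75, fit = NULL) {
  F_sq <- record$F_sq[paste0("q", q_range)]
  logF <- log10(F_sq)
  tension <- fit_tension_only_impl(logF, q_range, l_max)
  if (is.null(fit)) {
    fit <- fit_spectrum(record, temperature, q_range, l_max)
  }
  R_um <- record$mean_radius_um
  sigma <- if (is.na(R_um)) NA_real_ else
    .kB * temperature / (10^tension$log10_amplitude * (R_um * 1e-6)^2)
  list(epsilon_sigma_only = tension$epsilon,
       delta_epsilon = abs(fit$epsilon - tension$epsilon),
       sigma = sigma)
}

#' Durbin-Watson statistic of ordered fit residuals
#'
#' \eqn{DW = \sum_{i>1}(e_i - e_{i-1})^2 / \sum_i e_i^2}, bounded in
#' [0, 4]; 2 indicates uncorrelated residuals, values near 0 or 4
#' indicate positive or negative lag-1 autocorrelation (a symptom of a
#' systematically mis-shaped fit). Residuals are the per-mode log10
#' ratios in ascending q.
#'
#' @param residuals numeric vector, length >= 2.
#' @return scalar; NaN (with a warning) when all residuals are zero.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("all residuals are zero; Durbin-Watson undefined")
    return(NaN)
  }
  sum(diff(residuals)^2) / denom
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: sigma %.4g uN/m  kappa %.4g kBT  sigma_bar %.4g\n",
    x$sigma_uNm, x$kappa, x$sigma_bar))
  cat(sprintf("  eps %.4g  delta_eps %.4g  DW %.3f  converged %s\n",
              x$epsilon, x$delta_epsilon, x$durbin_watson, x$converged))
  invisible(x)
}
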
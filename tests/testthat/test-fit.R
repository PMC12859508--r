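# Brute-force summation oracle for the theoretical spectrum, written
# independently of the package implementation: explicit factorial
# normalization, term-by-term in plain doubles.
oracle_spectrum <- function(sigma_bar, kappa, q, l_max = 75) {
  total <- 0
  for (l in q:l_max) {
    if ((l + q) %% 2 == 1 || l < 2) next
    # P_l^q(0) via logs of the double factorials
    kp <- (l + q) / 2
    logP <- lgamma(l + q + 1) - kp * log(2) - lgamma(kp + 1) -
      ((l - q) / 2) * log(2) - lgamma((l - q) / 2 + 1)
    logN <- 0.5 * (log(2 * l + 1) - log(4 * pi) + lgamma(l - q + 1) -
                     lgamma(l + q + 1))
    NP2 <- exp(2 * (logN + logP))
    total <- total + NP2 / ((l + 2) * (l - 1) * (l * (l + 1) + sigma_bar))
  }
  total / kappa
}

test_that("theoretical spectrum agrees with the brute-force oracle to 12 digits", {
  set.seed(2024)
  for (i in 1:20) {
    sb <- 10^runif(1, -2, 6)
    kp <- 10^runif(1, -1, 3)
    q <- sample(2:15, 1)
    got <- theoretical_spectrum(sb, kp, q_range = q:q)
    expect_equal(unname(got), oracle_spectrum(sb, kp, q),
                 tolerance = 1e-12,
                 label = sprintf("sb=%.3g kp=%.3g q=%d", sb, kp, q))
  }
})

test_that("spectrum scaling laws: tension dominance and linear kappa prefactor", {
  th_huge <- theoretical_spectrum(1e12, 5)
  expect_lt(max(th_huge), 1e-13)
  th1 <- theoretical_spectrum(100, 1)
  th2 <- theoretical_spectrum(100, 2)
  expect_equal(unname(th1 / th2), rep(2, 14), tolerance = 1e-12)
  expect_error(theoretical_spectrum(100, 5, q_range = 2:20, l_max = 15),
               "l_max")
})

test_that("l_max = 75 is converged where it matters for fitting", {
  # per-mode tail: sub-0.5% in the bending/crossover regime; at very
  # large reduced tension the slowly decaying tail leaves a few percent
  # per mode, but the *fit* is insensitive to it (checked below)
  for (sb in c(1, 100)) {
    a <- theoretical_spectrum(sb, 5, l_max = 75)
    b <- theoretical_spectrum(sb, 5, l_max = 150)
    expect_lt(max(abs(a / b - 1)), 5e-3, label = sprintf("sigma_bar %g", sb))
  }
  # spectra generated at l_max = 150, fitted with the l_max = 75 model
  for (sb in c(1, 100)) {
    th150 <- theoretical_spectrum(sb, 5, l_max = 150)
    rec <- structure(list(F_sq = setNames(th150, paste0("q", 2:15)),
                          mean_radius_um = 2), class = "spectrum_record")
    f <- fit_spectrum(rec, 298, l_max = 75)
    expect_lt(abs(f$sigma_bar / sb - 1), 0.05,
              label = sprintf("sigma_bar %g", sb))
    expect_lt(abs(f$kappa / 5 - 1), 0.05,
              label = sprintf("kappa at sigma_bar %g", sb))
  }
  # deep in the tension regime only sigma = sigma_bar*kappa/R^2 is
  # identified (the spectrum is kappa-free); the physical tension is
  # still recovered and the Delta-epsilon diagnostic flags the record
  th150 <- theoretical_spectrum(1e4, 5, l_max = 150)
  rec <- structure(list(F_sq = setNames(th150, paste0("q", 2:15)),
                        mean_radius_um = 2), class = "spectrum_record")
  f <- fit_spectrum(rec, 298, l_max = 75)
  sig_true <- 1e4 * 5 * kB * 298 / (2e-6)^2
  expect_lt(abs(f$sigma / sig_true - 1), 0.05)
  expect_lt(f$delta_epsilon, 0.03)   # bending not identifiable here
})

test_that("spectral error arithmetic follows the log10 definition", {
  th <- theoretical_spectrum(300, 5)
  expect_equal(spectral_error(th, th), 0)
  expect_equal(spectral_error(10 * th, th), 14, tolerance = 1e-12)
  one_off <- th
  one_off[5] <- 100 * one_off[5]
  expect_equal(spectral_error(one_off, th), 4, tolerance = 1e-12)
  expect_error(spectral_error(th, -th), "positive")
})

test_that("fitting the model to itself recovers parameters within 1%", {
  for (truth in list(c(300, 5), c(20, 0.8), c(3e4, 50))) {
    th <- theoretical_spectrum(truth[1], truth[2])
    rec <- structure(list(F_sq = setNames(th, paste0("q", 2:15)),
                          mean_radius_um = 2), class = "spectrum_record")
    f <- fit_spectrum(rec, 298)
    expect_lt(abs(f$sigma_bar / truth[1] - 1), 0.01)
    expect_lt(abs(f$kappa / truth[2] - 1), 0.01)
    expect_lt(f$epsilon, 1e-6)
    # sigma = sigma_bar * kappa_J / R^2
    sig_expect <- truth[1] * truth[2] * kB * 298 / (2e-6)^2
    expect_equal(f$sigma, sig_expect, tolerance = 0.02)
  }
})

test_that("refined error never exceeds the grid initialization error", {
  set.seed(5)
  for (i in 1:5) {
    noisy <- theoretical_spectrum(10^runif(1, 0, 3), 10^runif(1, -0.5, 1.5)) *
      exp(rnorm(14, sd = 0.3))
    rec <- structure(list(F_sq = setNames(noisy, paste0("q", 2:15)),
                          mean_radius_um = 1.5), class = "spectrum_record")
    f <- fit_spectrum(rec, 298)
    # recompute the grid minimum with the same settings
    grid_eps <- Inf
    for (lsb in seq(-4, 10, by = 1 / 8)) {
      th <- theoretical_spectrum(10^lsb, 1)
      r <- log10(th) - log10(noisy)
      lk <- mean(r)                 # optimal log10 kappa, closed form
      grid_eps <- min(grid_eps, sum((r - round(lk * 8) / 8)^2))
    }
    expect_lte(f$epsilon, grid_eps + 1e-9)
  }
})

test_that("fine-grid search lands in the same basin as grid + downhill", {
  th <- theoretical_spectrum(300, 5)
  lsb <- seq(-4, 10, length.out = 200)
  lkp <- seq(-3, 11, length.out = 200)
  eps <- outer(lsb, lkp, Vectorize(function(a, b) {
    sum((log10(theoretical_spectrum(10^a, 10^b)) - log10(th))^2)
  }))
  ix <- arrayInd(which.min(eps), dim(eps))
  rec <- structure(list(F_sq = setNames(th, paste0("q", 2:15)),
                        mean_radius_um = 2), class = "spectrum_record")
  f <- fit_spectrum(rec, 298)
  expect_lt(abs(lsb[ix[1]] - log10(f$sigma_bar)), 0.1)
  expect_lt(abs(lkp[ix[2]] - log10(f$kappa)), 0.1)
})

test_that("tension-only comparison separates tension- and bending-dominated spectra", {
  # tension-only truth: both models fit, delta small
  tq <- flickerspec:::tension_only_shape()
  rec_t <- structure(list(F_sq = setNames(tq * 1e-4, paste0("q", 2:15)),
                          mean_radius_um = 2), class = "spectrum_record")
  f_t <- fit_spectrum(rec_t, 298)
  expect_lt(f_t$delta_epsilon, 0.03)
  # bending-dominated truth: tension-only fit clearly worse
  th_b <- theoretical_spectrum(0.01, 0.5)
  rec_b <- structure(list(F_sq = setNames(th_b, paste0("q", 2:15)),
                          mean_radius_um = 2), class = "spectrum_record")
  f_b <- fit_spectrum(rec_b, 298)
  expect_gt(f_b$delta_epsilon, 0.03)
  expect_gte(f_b$delta_epsilon, 0)
  ft <- fit_tension_only(rec_b, 298, fit = f_b)
  expect_equal(ft$delta_epsilon, f_b$delta_epsilon)
})

test_that("Durbin-Watson arithmetic and distributional behavior", {
  expect_equal(durbin_watson(rep(0.3, 10)), 0)
  alt <- 0.2 * (-1)^(1:14)
  expect_equal(durbin_watson(alt), 52 / 14, tolerance = 1e-12)
  set.seed(8)
  dws <- replicate(200, durbin_watson(rnorm(500)))
  expect_equal(mean(dws), 2, tolerance = 0.05)
  expect_warning(dw0 <- durbin_watson(c(0, 0, 0)), "undefined")
  expect_true(is.nan(dw0))
  expect_error(durbin_watson(1), "at least 2")
})

test_that("parameter recovery improves with the number of frames", {
  errs <- vapply(c(200, 1000), function(nf) {
    e <- vapply(1:6, function(s) {
      p <- params_for_sigma_bar(300, kappa = 5)
      rec <- simulate_spectrum_record(p, nf, 0, seed = 400 + s)
      f <- fit_spectrum(rec, 298)
      (abs(f$sigma_bar / 300 - 1) + abs(f$kappa / 5 - 1)) / 2
    }, numeric(1))
    median(e)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.2)
})
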
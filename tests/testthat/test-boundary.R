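test_that("directional gradient of a linear ramp is cos(phi) everywhere usable", {
  n <- 41
  img <- matrix(rep(0:(n - 1), each = n), n, n)   # I(x, y) = x
  fld <- build_field(img, c(20, 20), smoothing_width = 0, mode = "condensate")
  X <- matrix(0:(n - 1), n, n, byrow = TRUE) - 20
  Y <- matrix(0:(n - 1), n, n) - 20
  phi <- atan2(Y, X)
  diff <- abs(fld$field - cos(phi))
  diff[21, 21] <- 0   # gradient direction undefined at the center pixel
  core <- 3:(n - 2)   # away from the replicated edge padding
  expect_lt(max(diff[core, core]), 1e-12)
})

test_that("5-point stencil is exact for quartics and a uniform image has zero gradient", {
  n <- 31
  xs <- 0:(n - 1)
  img <- matrix(rep(0.02 * xs^4 - 0.5 * xs^3 + xs^2 + 3 * xs, each = n),
                n, n)
  d <- flickerspec:::stencil_derivative(img, "x")
  expected <- 0.08 * xs^3 - 1.5 * xs^2 + 2 * xs + 3
  core <- 3:(n - 2)
  expect_equal(d[5, core], expected[core], tolerance = 1e-8)
  flat <- build_field(matrix(7, n, n), c(15, 15), 1, "condensate")
  expect_equal(max(abs(flat$field)), 0, tolerance = 1e-12)
})

test_that("sub-pixel accuracy: disk radii 10-40 px recovered within 1/15 px", {
  for (r_true in c(10, 20.4, 31, 40)) {
    frame <- 2 * ceiling(r_true) + 26
    img <- render_disk(r_true, frame = frame)
    cfg <- imaging_config(min_size = max(6, r_true), max_size = 3 * r_true)
    ct <- extract_contour(img, cfg)
    expect_true(ct$valid)
    expect_lt(abs(mean(ct$radii) - r_true), 1 / 15,
              label = sprintf("radius %.1f", r_true))
  }
})

test_that("ellipse boundary has dominant Fourier mode q = 2", {
  p <- simulation_params(radius = 2, pixel_size = 0.1, noise_sd = 0)
  phi <- 2 * pi * seq(0, 399) / 400
  # r(phi) for an axis-aligned ellipse, axes 22 and 18
  radii <- 22 * 18 / sqrt((18 * cos(phi))^2 + (22 * sin(phi))^2)
  img <- render_frame(contour_from_radii(radii), p, c(64, 64), c(32, 32))
  ct <- extract_contour(img, imaging_config(min_size = 20, max_size = 50))
  m <- contour_modes(ct)
  amp <- Mod(m$V[-1])   # q >= 1
  expect_equal(which.max(amp), 2)
  expect_gt(amp[2], 5 * max(amp[-2]))
})

test_that("rotation by 90 degrees permutes the contour angles", {
  phi <- 2 * pi * seq(0, 399) / 400
  radii <- 15 + 1.5 * cos(3 * phi) + 0.8 * sin(2 * phi)
  p <- simulation_params(radius = 2, pixel_size = 0.1, noise_sd = 0)
  img <- render_frame(contour_from_radii(radii), p, c(64, 64), c(32, 32))
  # rotate the image 90 deg counterclockwise about the pixel center
  imgr <- t(img)[ncol(img):1, ]
  cfg <- imaging_config(min_size = 18, max_size = 45)
  ct <- extract_contour(img, cfg)
  ctr <- extract_contour(imgr, cfg)
  # the rotated contour at angle psi equals the original at psi + 90 deg
  shifted <- c(ct$radii[101:400], ct$radii[1:100])
  expect_lt(max(abs(ctr$radii - shifted)), 0.1)
})

test_that("continuity validation flags fused doublets but passes circles", {
  p <- simulation_params(radius = 2, pixel_size = 0.1, noise_sd = 0)
  img <- render_disk(14, frame = 72)
  expect_true(validate_contour(extract_contour(
    img, imaging_config(min_size = 18, max_size = 40)), 3))
  # two touching discs traced from the doublet centroid (the pipeline's
  # center source): rays through the lobes see no boundary inside their
  # range and the neck makes the radial function jump
  fused <- render_frame(circle_contour(14), p, c(80, 96), c(26, 40)) +
    render_frame(circle_contour(14), p, c(80, 96), c(54, 40)) -
    p$background * 255
  cfgf <- imaging_config(min_size = 18, max_size = 40)
  ext <- estimate_extent(fused, c(40, 40), cfgf)
  expect_equal(ext$centroid, c(40, 40), tolerance = 0.1)
  bb <- ext$bbox
  sub <- fused[(bb[2]:bb[4]) + 1, (bb[1]:bb[3]) + 1, drop = FALSE]
  fld <- build_field(sub, ext$centroid - bb[1:2], 1, "condensate")
  ct <- trace_boundary(fld)
  expect_false(validate_contour(ct, 3))
  # a single flagged ray fails validation regardless of smoothness
  ct2 <- circle_contour(10)
  ct2$flags <- c(TRUE, rep(FALSE, 399))
  expect_false(validate_contour(ct2, 3))
})

test_that("vesicle mode finds a thin bright ring where gradient mode agrees", {
  # ring with sharp outer edge: intensity peak and max inward gradient
  # both sit at the membrane radius
  n <- 64
  X <- matrix(0:(n - 1), n, n, byrow = TRUE) - 32
  Y <- matrix(0:(n - 1), n, n) - 32
  d <- sqrt(X^2 + Y^2)
  r0 <- 18
  img <- 200 * exp(-(d - r0)^2 / (2 * 1.2^2)) + 10
  fldv <- build_field(img, c(32, 32), 1, "vesicle")
  ctv <- trace_boundary(fldv)
  expect_lt(abs(mean(ctv$radii) - r0), 0.1)
  fldc <- build_field(img, c(32, 32), 1, "condensate")
  ctc <- trace_boundary(fldc)
  # gradient peak of a Gaussian ring sits one blurred-sd outward
  sd_eff <- sqrt(1.2^2 + 1^2)
  expect_lt(abs(mean(ctc$radii) - (r0 + sd_eff)), 0.25)
})

test_that("resolution limit follows the tanh closed form", {
  a <- resolution_limit(zeta = 0.8, n_levels = 10, levels = 255)
  expect_equal(1 / a, 15.9, tolerance = 0.05 / 15.9)
  expect_equal(resolution_limit(zeta = 0.8, n_levels = 0), 0)
  expect_equal(resolution_limit(zeta = 1.6, n_levels = 10),
               2 * resolution_limit(zeta = 0.8, n_levels = 10))
  expect_error(resolution_limit(zeta = 0.8, n_levels = 200), "< 1")
})

test_that("contour noise response is monotone in the rendering noise level", {
  errs <- vapply(c(0, 0.02, 0.08), function(ns) {
    e <- numeric(3)
    for (s in 1:3) {
      img <- render_disk(15, frame = 56, noise_sd = ns, seed = 100 + s)
      ct <- extract_contour(img, imaging_config(min_size = 18,
                                                max_size = 42))
      e[s] <- mean(abs(ct$radii - 15))
    }
    mean(e)
  }, numeric(1))
  expect_true(all(diff(errs) >= 0),
              info = paste(round(errs, 4), collapse = " "))
})
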
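test_that("crafted 7-record set: one record passes, each filter rejects once", {
  records <- rbind(
    make_record(sigma = 1e-11),            # tension filter
    make_record(continuity = 0.5),         # continuity filter
    make_record(epsilon = 0.6),            # fit-error filter
    make_record(delta_epsilon = 0.01),     # model-comparison filter
    make_record(n_frames = 100),           # min-frames filter
    make_record(sigma = 1e-11, epsilon = 0.9),  # double violation: first wins
    make_record())                         # clean
  res <- apply_population_filters(records, filter_spec())
  expect_equal(nrow(res$records), 1)
  expect_equal(unname(res$rejections),
               c(2L, 1L, 1L, 1L, 1L))
  expect_equal(res$pass, c(rep(FALSE, 6), TRUE))
})

test_that("filter pass/fail is order-independent; boundary values excluded", {
  r <- make_record(sigma = 1e-10, epsilon = 0.5, delta_epsilon = 0.03,
                   continuity = 0.60)
  res <- apply_population_filters(r, filter_spec())
  expect_equal(nrow(res$records), 0)       # strict inequalities
  r2 <- make_record(n_frames = 200)
  expect_equal(nrow(apply_population_filters(r2, filter_spec())$records), 1)
  empty <- apply_population_filters(make_record()[0, ], filter_spec())
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$rejections), 0L)
})

test_that("geometric and arithmetic summaries", {
  s <- summarize_population(c(1, 100), "lognormal")
  expect_equal(s$center, 10)
  one <- summarize_population(5.3, "lognormal")
  expect_equal(one$spread, 1)
  set.seed(10)
  x <- exp(rnorm(1e4))
  sl <- summarize_population(x, "lognormal")
  expect_equal(sl$spread, exp(1), tolerance = 0.02)
  la <- summarize_population(c(2, 4, 6), "linear")
  expect_equal(la$center, 4)
  expect_equal(la$spread, 2)
  expect_error(summarize_population(c(-1, 2), "lognormal"), "positive")
})

test_that("aggregate HDF5 file round-trips records and survives empty sets", {
  tmp <- tempfile(fileext = ".h5")
  on.exit(unlink(tmp))
  rec <- flickerspec:::empty_aggregate()
  rec[1, ] <- list("v1", 0L, 1.2e-6, 1.2, 5.1, 300, 2.0, 0.05, 0.8, 0.75,
                   2.1, 950L, 0.95, 180.2, 33.1, 34.0, 1e-7, 0.4, TRUE,
                   "exp", 0)
  rec[2, ] <- list("v1", 1L, 8e-7, 0.8, 3.3, 150, 1.5, 0.21, 0.4, 0.19,
                   1.8, 400L, 0.80, 120.9, 71.2, 35.5, 2e-7, 0.6, FALSE,
                   "exp", 1)
  write_aggregate(rec, tmp)
  back <- read_aggregate(tmp)
  expect_equal(back, rec, tolerance = 1e-12)
  empty <- flickerspec:::empty_aggregate()
  tmp2 <- tempfile(fileext = ".h5")
  on.exit(unlink(tmp2), add = TRUE)
  write_aggregate(empty, tmp2)
  expect_equal(nrow(read_aggregate(tmp2)), 0)
})

test_that("1000 synthetic records keep types and count through HDF5", {
  n <- 1000
  rec <- flickerspec:::empty_aggregate()
  set.seed(3)
  rec <- data.frame(video = rep("v", n), object_id = seq_len(n) - 1L,
                    sigma = 10^rnorm(n, -6), sigma_uNm = 10^rnorm(n, 0),
                    kappa = 10^rnorm(n, 0.7), sigma_bar = 10^rnorm(n, 2),
                    mean_radius_um = runif(n, 0.5, 4),
                    epsilon = runif(n), epsilon_sigma_only = runif(n),
                    delta_epsilon = runif(n), durbin_watson = runif(n, 0, 4),
                    n_frames = sample(1000, n), continuity = runif(n),
                    mean_intensity = runif(n, 0, 255),
                    cx = runif(n, 0, 512), cy = runif(n, 0, 512),
                    se_sigma = runif(n), se_kappa = runif(n),
                    converged = sample(c(TRUE, FALSE), n, replace = TRUE),
                    experiment = rep("e", n), timestamp = as.numeric(1:n),
                    stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".h5")
  on.exit(unlink(tmp))
  write_aggregate(rec, tmp)
  back <- read_aggregate(tmp)
  expect_equal(nrow(back), n)
  expect_identical(vapply(back, class, character(1)),
                   vapply(rec, class, character(1)))
  expect_equal(back$sigma, rec$sigma)
  expect_identical(back$converged, rec$converged)
})

test_that("OME-TIFF round-trip preserves frames and pixel size", {
  p <- simulation_params(radius = 1.2, pixel_size = 0.08)
  vid <- generate_video(p, n_frames = 3, n_objects = 1, seed = 2)
  tmp <- tempfile(fileext = ".ome.tif")
  on.exit(unlink(tmp))
  write_frame_stack(vid$stack, tmp)
  back <- read_frame_stack(tmp)
  expect_equal(length(back), 3)
  expect_identical(back$frames, vid$stack$frames)
  expect_equal(back$pixel_size, 0.08)
})

test_that("16-bit stacks round-trip", {
  f <- list(matrix(c(0, 4464, 300, 65535), 2, 2))
  st <- frame_stack(f, pixel_size = 0.1, bit_depth = 16)
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  write_frame_stack(st, tmp)
  back <- read_frame_stack(tmp)
  expect_identical(back$frames[[1]], f[[1]])
  expect_equal(back$bit_depth, 16L)
})

test_that("plain TIFF without pixel size errors; override supplies it", {
  st <- frame_stack(list(matrix(as.numeric(1:20), 4, 5)),
                    pixel_size = NA_real_)
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  write_frame_stack(st, tmp, ome = FALSE)
  expect_error(read_frame_stack(tmp), "pixel size missing")
  back <- read_frame_stack(tmp, pixel_size_override = 0.2)
  expect_equal(back$pixel_size, 0.2)
  expect_identical(back$frames[[1]], matrix(as.numeric(1:20), 4, 5))
  expect_error(read_frame_stack(tempfile()), "not found")
})

test_that("a 133-frame stack reports 133 frames", {
  frames <- replicate(133, matrix(0L, 6, 6), simplify = FALSE)
  st <- frame_stack(frames, pixel_size = 0.1)
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  write_frame_stack(st, tmp)
  expect_equal(length(read_frame_stack(tmp)), 133)
})

test_that("config parsing validates keys and demands videos", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfgf <- file.path(dir, "exp.yaml")
  writeLines(c("experiment_name: demo", "pixel_size: 0.1",
               "videos:", "  - a.tif", "min_size: 12", "max_size: 30"),
             cfgf)
  cfg <- read_experiment_config(cfgf)
  expect_equal(cfg$name, "demo")
  expect_equal(cfg$config$min_size, 12)
  expect_equal(cfg$filters$min_frames, 200)
  writeLines(c("videos:", "  - a.tif", "spellling_mistake: 1"), cfgf)
  expect_error(read_experiment_config(cfgf), "unknown configuration keys")
  writeLines("experiment_name: x", cfgf)
  expect_error(read_experiment_config(cfgf), "at least one video")
})
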
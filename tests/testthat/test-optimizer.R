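test_that("F1 is the sum of per-video worst-frame usable counts", {
  counts <- data.frame(video = c(1, 1, 2, 2),
                       usable = c(3, 5, 2, 4),
                       unusable = c(2, 4, 0, 0))
  expect_equal(objective_usable(counts), 5)        # 3 + 2
  expect_equal(objective_unusable(counts), -1.5)   # -(3 + 0)/2
  zero <- data.frame(video = 1:2, usable = 0, unusable = 0)
  expect_equal(objective_usable(zero), 0)
  expect_equal(objective_unusable(zero), 0)
  # adding a worse frame can only lower a video's term
  counts2 <- rbind(counts, data.frame(video = 1, usable = 1, unusable = 0))
  expect_lte(objective_usable(counts2), objective_usable(counts))
  expect_lte(objective_unusable(counts), 0)
})

test_that("subset sampling respects the 12-video cap and is seeded", {
  spec <- optimizer_spec(seed = 4)
  s3 <- sample_subset(rep(100, 3), spec)
  expect_equal(length(unique(s3$video)), 3)
  expect_equal(nrow(s3), 6)
  s30 <- sample_subset(rep(50, 30), spec)
  expect_equal(length(unique(s30$video)), 12)
  expect_equal(nrow(s30), 24)
  expect_true(all(s30$frame >= 0 & s30$frame < 50))
  expect_identical(sample_subset(rep(50, 30), spec),
                   sample_subset(rep(50, 30), spec))
})

# 1-D toy problem on a 100-point grid of min_intensity in [0, 1]:
# usable rises then falls, unusable falls monotonically with threshold,
# so the lexicographic optimum sits right of the F1 peak.
toy_grid <- seq(0, 1, length.out = 100)
toy_usable <- function(t) round(12 * exp(-(t - 0.45)^2 / (2 * 0.18^2)))
toy_unusable <- function(t) round(9 * (1 - t)^2)
toy_evaluator <- function(theta) {
  t <- toy_grid[which.min(abs(toy_grid - theta[["min_intensity"]]))]
  data.frame(video = c(1, 1, 2, 2), frame = c(0, 1, 0, 1),
             usable = toy_usable(t), unusable = toy_unusable(t))
}
toy_oracle <- function(fraction = 0.9) {
  F1 <- vapply(toy_grid, function(t) 2 * toy_usable(t), numeric(1))
  F2 <- vapply(toy_grid, function(t) -toy_unusable(t), numeric(1))
  n_max <- max(F1)
  feasible <- F1 >= fraction * n_max
  list(n_max = n_max, best_F2 = max(F2[feasible]),
       best_t = toy_grid[feasible][which.max(F2[feasible])])
}

test_that("toy lexicographic optimization matches the exhaustive grid oracle", {
  spec <- optimizer_spec(parameter_bounds = list(min_intensity = c(0, 1)),
                         budget = 40, seed = 11)
  res <- optimize_parameters(NULL, spec, evaluator = toy_evaluator,
                             n_frames_per_stack = c(2, 2))
  oracle <- toy_oracle()
  expect_equal(res$n_max, oracle$n_max)
  expect_gte(res$F1, 0.9 * res$n_max)
  expect_true(res$feasible)
  expect_equal(res$F2, oracle$best_F2)
  # determinism: same seed, same result
  res2 <- optimize_parameters(NULL, spec, evaluator = toy_evaluator,
                              n_frames_per_stack = c(2, 2))
  expect_identical(res$theta, res2$theta)
})

test_that("optimizer never evaluates outside the box and aborts when nothing is usable", {
  seen <- new.env(); seen$min <- Inf; seen$max <- -Inf
  ev <- function(theta) {
    t <- theta[["min_intensity"]]
    seen$min <- min(seen$min, t); seen$max <- max(seen$max, t)
    data.frame(video = 1, frame = 0, usable = round(5 * t), unusable = 0)
  }
  spec <- optimizer_spec(parameter_bounds = list(min_intensity = c(0.2, 0.8)),
                         budget = 12, n_init = 4, seed = 3)
  res <- optimize_parameters(NULL, spec, evaluator = ev,
                             n_frames_per_stack = 1)
  expect_gte(seen$min, 0.2)
  expect_lte(seen$max, 0.8)
  expect_gte(res$F1, 0)
  ev0 <- function(theta) data.frame(video = 1, frame = 0, usable = 0,
                                    unusable = 3)
  expect_error(optimize_parameters(NULL, spec, evaluator = ev0,
                                   n_frames_per_stack = 1),
               "no usable objects")
})

test_that("on synthetic frames the optimizer finds parameters that detect the droplets", {
  p <- simulation_params(radius = 1.5, pixel_size = 0.1)
  vid <- generate_video(p, n_frames = 4, n_objects = 2, seed = 13)
  spec <- optimizer_spec(parameter_bounds = list(min_intensity = c(0.05, 0.9),
                                                 min_size = c(8, 28)),
                         budget = 14, n_init = 6, seed = 2)
  res <- optimize_parameters(list(vid$stack), spec,
                             base_config = imaging_config(min_size = 20,
                                                          max_size = 45))
  expect_gte(res$n_max, 1)
  expect_gte(res$F1, 0.9 * res$n_max)
  # held-out frame: the recommended parameters find both droplets
  held <- generate_video(p, n_frames = 1, n_objects = 2, seed = 14)
  cfg <- imaging_config(min_intensity = res$theta[["min_intensity"]],
                        min_size = res$theta[["min_size"]],
                        max_size = 45)
  expect_gte(nrow(detect_centers(held$stack$frames[[1]], cfg)), 2)
})
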
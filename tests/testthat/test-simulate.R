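test_that("speed process: noiseless dynamics behave as a deterministic ODE", {
  # fixed point: start at the mean with no noise -> constant
  gp <- genotype_params("g", mu_speed = 0.1, theta = 0.7, sigma = 0)
  v <- simulate_speed_trace(gp, n_steps = 50, dt = 1, seed = 1, v0 = 0.1)
  expect_equal(v, rep(0.1, 50))

  # relaxation: start far below the mean -> monotone approach to mu
  gp2 <- genotype_params("g", mu_speed = 0.15, theta = 0.3, sigma = 0)
  v2 <- simulate_speed_trace(gp2, n_steps = 60, dt = 1, seed = 1, v0 = 0.001)
  expect_true(all(diff(v2) > 0))
  expect_lt(abs(v2[60] - 0.15), 1e-6)
  expect_true(all(v2 <= 0.15))
})

test_that("speed process: reproducible, nonnegative, mean-reverting", {
  gp <- genotype_preset("wildtype")
  v1 <- simulate_speed_trace(gp, 500, dt = 1, seed = 42)
  v2 <- simulate_speed_trace(gp, 500, dt = 1, seed = 42)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0))
  v3 <- simulate_speed_trace(gp, 5000, dt = 1, seed = 7)
  expect_lt(abs(mean(v3) - gp$mu_speed), 5 * stationary_speed_sd(gp) / sqrt(5000 / 10))
  expect_error(simulate_speed_trace(gp, 10, dt = 0, seed = 1), "dt")
  expect_error(genotype_params("g", 0.1, theta = 0, sigma = 0.01), "theta")
})

test_that("trajectories: straight motion, stationarity, determinism, bounds", {
  # constant speed, no turning, heading 0 -> straight line in x
  pos <- simulate_trajectory(rep(0.1, 10), turn_sd = 0, start = c(1, 1),
                             arena_mm = c(10, 10), dt = 1, seed = 1,
                             heading0 = 0)
  expect_equal(pos[, "x"], 1 + 0.1 * (0:10))
  expect_equal(pos[, "y"], rep(1, 11))

  # zero speed -> stationary point
  pos0 <- simulate_trajectory(rep(0, 5), turn_sd = 0.5, start = c(2, 3),
                              arena_mm = c(10, 10), seed = 9)
  expect_equal(unname(pos0), matrix(rep(c(2, 3), each = 6), ncol = 2))

  # same inputs, same seed -> identical paths
  v <- simulate_speed_trace(genotype_preset("wildtype"), 60, 1, seed = 3)
  p1 <- simulate_trajectory(v, 0.5, c(20, 20), c(40, 40), seed = 11)
  p2 <- simulate_trajectory(v, 0.5, c(20, 20), c(40, 40), seed = 11)
  expect_identical(p1, p2)

  # displacement magnitude equals speed * dt when no wall is hit
  # (start at the centre of a large arena so no reflection occurs)
  disp <- sqrt(diff(p1[, 1])^2 + diff(p1[, 2])^2)
  expect_equal(disp, v, tolerance = 1e-12)

  # paths stay inside the arena even when reflecting (tiny arena forces it)
  pfast <- simulate_trajectory(rep(0.4, 200), 0.3, c(0.5, 0.5), c(1.5, 1.5),
                               seed = 4)
  expect_true(all(pfast >= 0 & pfast[, 1] <= 1.5 & pfast[, 2] <= 1.5))

  expect_error(
    simulate_trajectory(rep(0.1, 5), 0, c(-1, 5), c(10, 10), seed = 1),
    "inside the arena")
})

test_that("generate_dataset conserves counts and ground truth", {
  cfg <- sim_config(n_animals = 1, duration_s = 120, dt = 1,
                    dropout_prob = 0, arena_mm = c(40, 40), seed = 5)
  ds <- generate_dataset(cfg, genotype_preset("wildtype"),
                         starts = cbind(20, 20))
  per_frame <- table(ds$detections$frame)
  expect_equal(length(per_frame), 121L)  # 2 min at 1 Hz inclusive of t = 0
  expect_true(all(per_frame == 1L))

  # with no dropout, emitted centroids equal true positions exactly
  tr <- ds$truth[order(ds$truth$frame, ds$truth$y_mm, ds$truth$x_mm), ]
  expect_equal(ds$detections$x_mm, tr$x_mm)
  expect_equal(ds$detections$y_mm, tr$y_mm)

  # true speed matches per-frame displacement (no reflection: the animal
  # starts at the centre of a 40 mm arena)
  disp <- sqrt(diff(ds$truth$x_mm)^2 + diff(ds$truth$y_mm)^2)
  expect_equal(disp, ds$truth$true_speed_mm_s[-nrow(ds$truth)],
               tolerance = 1e-12)

  # determinism: same config -> bit-identical outputs
  ds2 <- generate_dataset(cfg, genotype_preset("wildtype"),
                          starts = cbind(20, 20))
  expect_identical(ds$detections, ds2$detections)
  expect_identical(ds$truth, ds2$truth)
})

test_that("detection dropout is binomial at the configured rate", {
  cfg <- sim_config(n_animals = 40, duration_s = 120, dropout_prob = 0.5,
                    arena_mm = c(20, 20), seed = 8)
  ds <- generate_dataset(cfg, genotype_preset("wildtype"))
  n_expected <- 40 * 121 * 0.5
  sd_expected <- sqrt(40 * 121 * 0.25)
  expect_lt(abs(nrow(ds$detections) - n_expected), 4 * sd_expected)
})

test_that("arena too small for the requested animal spacing errors", {
  cfg <- sim_config(n_animals = 50, duration_s = 10, arena_mm = c(3, 3),
                    min_spacing_mm = 1, seed = 1)
  expect_error(generate_dataset(cfg, genotype_preset("wildtype")),
               "too small")
})

test_that("rendered frames put blob mass where the animals are", {
  # intensity-weighted centroid of one rendered blob recovers the position
  img <- render_frame(c(0.50, 0.80), image_dim = c(120, 120),
                      mm_per_px = 0.01, blob_sigma = 2)
  w <- sum(img)
  cx <- sum(img * col(img)) / w
  cy <- sum(img * row(img)) / w
  expect_lt(abs(cx - (0.50 / 0.01 + 0.5)), 0.1)
  expect_lt(abs(cy - (0.80 / 0.01 + 0.5)), 0.1)

  # zero animals -> uniform background
  bg <- render_frame(matrix(numeric(0), ncol = 2), c(50, 50),
                     background = 0.2)
  expect_equal(bg, matrix(0.2, 50, 50))

  # two far-apart blobs -> two local maxima at the two positions
  img2 <- render_frame(rbind(c(0.2, 0.2), c(0.8, 0.9)), c(120, 120))
  expect_equal(sum(img2), 2 * sum(img), tolerance = 0.01)
  # blob centres fall between pixel centres, so the brightest pixel holds
  # exp(-0.5^2 / (2 sigma^2)) ~ 0.97 of the peak
  pk1 <- img2[0.2 / 0.01 + 0.5, 0.2 / 0.01 + 0.5]
  pk2 <- img2[0.9 / 0.01 + 0.5, 0.8 / 0.01 + 0.5]
  expect_gt(pk1, 0.9)
  expect_gt(pk2, 0.9)
  expect_error(render_frame(c(5, 5), c(100, 100), mm_per_px = 0.01),
               "outside the image")
})
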
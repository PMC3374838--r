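test_that("raw speed is path distance over time, direction-blind", {
  tr <- make_track(cbind(c(0, 0.1, 0.2), 0))
  expect_equal(raw_speed(tr), c(0.1, 0.1))
  expect_equal(raw_speed(make_track(cbind(rep(1, 5), 2))), rep(0, 4))
  # square path: constant speed despite turning
  sq <- make_track(rbind(c(0, 0), c(0.1, 0), c(0.1, 0.1), c(0, 0.1), c(0, 0)))
  expect_equal(raw_speed(sq), rep(0.1, 4))
  bad <- tibble::tibble(time_s = c(0, 1, 3), x_mm = 0:2, y_mm = 0)
  expect_error(raw_speed(bad), "uniform")
})

test_that("sliding-window smoothing emits full trailing windows", {
  expect_equal(smooth_speed(1:5), 3)
  expect_equal(smooth_speed(rep(0.2, 12)), rep(0.2, 8))
  expect_equal(smooth_speed(c(0, 0, 0, 0, 5, 0, 0, 0, 0)), rep(1, 5))
  expect_error(smooth_speed(1:4), "too short")
  # window is a parameter
  expect_equal(smooth_speed(c(1, 3, 5), window = 2), c(2, 4))
})

test_that("acceleration is the first difference over dt", {
  expect_equal(acceleration(c(0.1, 0.1, 0.1)), c(0, 0))
  expect_equal(acceleration(c(0.1, 0.2), dt = 1), 0.1)
  ramp <- seq(0, 1, by = 0.05)
  expect_equal(acceleration(ramp, dt = 0.5), rep(0.1, 20))
  expect_error(acceleration(0.3), "at least 2")
})

test_that("event segmentation splits runs at zero crossings", {
  ev <- segment_events(c(0.1, 0.2, -0.1, -0.3, 0.05))
  expect_equal(ev$sign, c("+", "-", "+"))
  expect_equal(ev$duration_s, c(2, 2, 1))
  expect_equal(ev$peak, c(0.2, -0.3, 0.05))
  expect_equal(ev$start_s, c(0, 2, 4))

  expect_equal(nrow(segment_events(rep(0, 10))), 0L)
  expect_equal(nrow(segment_events(numeric(0))), 0L)

  # single sign throughout -> one event spanning the series
  ev1 <- segment_events(c(-1, -2, -0.5), dt = 2)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$duration_s, 6)
  expect_equal(ev1$peak, -2)

  # exact zeros terminate events and join neither sign
  ev0 <- segment_events(c(1, 0, 1))
  expect_equal(nrow(ev0), 2L)
  expect_equal(ev0$duration_s, c(1, 1))
})

test_that("event segmentation agrees with the state-machine oracle", {
  set.seed(52)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    a <- round(rnorm(n), 2)
    a[sample(n, size = floor(n / 4))] <- 0  # force exact zeros
    got <- segment_events(a, dt = 0.5)
    want <- oracle_segment_events(a, dt = 0.5)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    # events reconstruct the sign pattern: durations cover all nonzeros
    expect_equal(sum(got$duration_s), sum(a != 0) * 0.5)
  }
})

test_that("track_stats computes the per-track scalars", {
  # constant-speed track: no fluctuation, no acceleration, no events
  # (0.25 is exactly representable, so the acceleration is exactly zero)
  st <- track_stats(make_straight_track(rep(0.25, 40)))
  expect_equal(st$avg_speed, 0.25)
  expect_equal(st$speed_sd, 0)
  expect_equal(st$speed_cv, 0)
  expect_equal(st$rms_accel, 0)
  expect_equal(st$n_events_pos + st$n_events_neg, 0L)
  expect_true(is.na(st$mean_event_duration))

  # smoothed speeds exactly [0.1, 0.2, 0.3]: known mean, SD, CV
  raw <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.6, 0.6)
  expect_equal(smooth_speed(raw), c(0.1, 0.2, 0.3))
  st2 <- track_stats(make_straight_track(raw))
  expect_equal(st2$avg_speed, 0.2)
  expect_equal(st2$speed_sd, 0.1)  # sample SD, n - 1 denominator
  expect_equal(st2$speed_cv, 0.5)
  # accel series is [0.1, 0.1]: rms = 0.1, one + event of duration 2
  expect_equal(st2$rms_accel, 0.1)
  expect_equal(st2$n_events_pos, 1L)
  expect_equal(st2$mean_event_duration, 2)
  expect_equal(st2$mean_peak_accel, 0.1)
  expect_true(is.na(st2$mean_peak_decel))

  # stationary track: zero average speed, CV undefined
  st3 <- track_stats(make_track(cbind(rep(2, 10), 3)))
  expect_equal(st3$avg_speed, 0)
  expect_true(is.na(st3$speed_cv))

  # rms of a known acceleration series
  expect_equal(sqrt(mean(c(3, 4)^2)), sqrt(12.5))
})

test_that("smoothing is a variance contraction on random tracks", {
  set.seed(61)
  for (i in 1:100) {
    raw <- abs(rnorm(sample(10:80, 1), mean = 0.15, sd = 0.05))
    expect_lte(sd(smooth_speed(raw)), sd(raw) + 1e-12)
  }
})

test_that("bridged gaps are linearly interpolated before kinematics", {
  tr <- make_straight_track(rep(0.1, 10))
  gap <- tr[-c(4, 5), ]  # drop two interior frames
  filled <- interpolate_gaps(gap)
  expect_equal(nrow(filled), 11L)
  expect_equal(filled$x_mm, tr$x_mm)
  expect_equal(sum(filled$interpolated), 2L)
  # stats on the gapped track equal stats on the full track (linear path)
  expect_equal(track_stats(gap)$avg_speed, track_stats(tr)$avg_speed)
})

test_that("measured raw-speed SD approaches the process stationary SD", {
  gp <- genotype_params("g", mu_speed = 0.2, theta = 1, sigma = 0.05,
                        turn_sd = 0.4)
  v <- simulate_speed_trace(gp, 4000, dt = 1, seed = 77)
  pos <- simulate_trajectory(v[-4000], gp$turn_sd, c(100, 100), c(200, 200),
                             seed = 78)
  tr <- make_track(pos)
  measured <- sd(raw_speed(tr))
  expect_lt(abs(measured / stationary_speed_sd(gp) - 1), 0.1)
  # smoothing attenuates the fluctuation measure
  expect_lte(sd(smooth_speed(raw_speed(tr))), measured)
})
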
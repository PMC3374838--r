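test_that("assignment_step matches exhaustive minimum-cost matching", {
  # the canonical crossing case: optimal matching is not the row-greedy one
  heads <- rbind(c(0, 0), c(1, 0))
  dets <- rbind(c(0.9, 0), c(0.1, 0))
  m <- assignment_step(heads, dets, max_disp = 2)
  expect_equal(m, c(2L, 1L))

  # single admissible pair / inadmissible pair / empty detections
  expect_equal(assignment_step(c(0, 0), c(0.05, 0), 0.3), 1L)
  expect_equal(assignment_step(c(0, 0), c(5, 0), 0.3), NA_integer_)
  expect_equal(assignment_step(rbind(c(0, 0), c(1, 1)),
                               matrix(numeric(0), ncol = 2), 0.3),
               rep(NA_integer_, 2))
  expect_error(assignment_step(c(0, 0), c(1, 1), max_disp = 0), "positive")

  # random instances against the brute-force oracle
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:4, 1); m_ <- sample(1:4, 1)
    heads <- matrix(runif(2 * n), ncol = 2)
    dets <- matrix(runif(2 * m_), ncol = 2)
    gate <- runif(1, 0.2, 1.2)
    got <- matching_summary(heads, dets,
                            assignment_step(heads, dets, gate))
    want <- oracle_assignment(heads, dets, gate)
    expect_equal(got$cardinality, want$cardinality)
    expect_equal(got$cost, want$cost, tolerance = 1e-6)
  }
})

test_that("assignment is invariant to detection order", {
  set.seed(33)
  heads <- matrix(runif(10), ncol = 2)
  dets <- matrix(runif(12), ncol = 2)
  m1 <- assignment_step(heads, dets, 0.6)
  perm <- sample(nrow(dets))
  m2 <- assignment_step(heads, dets[perm, ], 0.6)
  # matched detection *positions* must agree
  expect_equal(dets[m1, ], dets[perm, ][m2, ])
})

test_that("one animal with no dropout yields one full-length track", {
  ds <- parallel_lane_dataset(1, spacing = 2.5, seed = 14, duration_s = 60)
  tr <- link_tracks(ds$detections, max_disp = 0.5, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 61L)
  expect_equal(tr$x_mm, ds$truth$x_mm)
})

test_that("well-separated animals are recovered with their identities", {
  ds <- parallel_lane_dataset(2, spacing = 3, seed = 15, duration_s = 60)
  tr <- link_tracks(ds$detections, max_disp = 0.5, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 2L)
  m <- merge(tr, ds$truth, by = c("frame", "x_mm", "y_mm"))
  expect_equal(nrow(m), nrow(ds$truth))
  # every recovered track maps to exactly one true animal and vice versa
  cross <- table(m$track_id, m$animal_id)
  expect_equal(sort(as.vector(cross)), c(0, 0, 61, 61))
})

test_that("gap bridging follows max_gap exactly", {
  det <- tibble::tibble(frame = c(1, 2, 4, 5),
                        time_s = c(0, 1, 3, 4),
                        x_mm = c(0, 0.1, 0.3, 0.4), y_mm = 0)
  tr1 <- link_tracks(det, max_disp = 0.5, max_gap = 1)
  expect_equal(length(unique(tr1$track_id)), 1L)
  expect_equal(nrow(tr1), 4L)
  tr0 <- link_tracks(det, max_disp = 0.5, max_gap = 0)
  expect_equal(length(unique(tr0$track_id)), 2L)
})

test_that("every detection lands in a track or among the singletons", {
  cfg <- sim_config(n_animals = 8, duration_s = 60, dropout_prob = 0.3,
                    arena_mm = c(12, 12), seed = 19)
  ds <- generate_dataset(cfg, genotype_preset("wildtype"))
  tr <- link_tracks(ds$detections, max_disp = 0.5, max_gap = 2)
  singles <- attr(tr, "singletons")
  expect_equal(nrow(tr) + nrow(singles), nrow(ds$detections))
  # no detection is claimed twice
  key <- function(d) paste(d$frame, d$x_mm, d$y_mm)
  expect_equal(anyDuplicated(c(key(tr), key(singles))), 0L)
})

test_that("filter_tracks keeps exactly the tracks long enough", {
  mk <- function(id, dur) {
    tibble::tibble(track_id = id, frame = 0:dur + 1L, time_s = 0:dur,
                   x_mm = 0, y_mm = 0)
  }
  tracks <- dplyr::bind_rows(mk(1, 20), mk(2, 30), mk(3, 53))
  kept <- filter_tracks(tracks, 30)
  expect_setequal(unique(kept$track_id), c(2, 3))
  expect_identical(filter_tracks(tracks, 0), tracks)
  expect_equal(nrow(filter_tracks(tracks, 60)), 0L)
})
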
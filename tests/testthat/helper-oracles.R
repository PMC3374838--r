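# Independent brute-force oracles and small fixture builders.

# State-machine enumeration of same-sign acceleration runs, written without
# rle() so it is independent of the implementation path it checks.
oracle_segment_events <- function(accel, dt = 1, t0 = 0) {
  events <- list()
  cur_sign <- 0
  cur_start <- NA_integer_
  flush <- function(i_end) {
    if (cur_sign == 0) return()
    seg <- accel[cur_start:i_end]
    events[[length(events) + 1L]] <<- data.frame(
      sign = if (cur_sign > 0) "+" else "-",
      start_s = t0 + (cur_start - 1L) * dt,
      end_s = t0 + i_end * dt,
      duration_s = (i_end - cur_start + 1L) * dt,
      peak = if (cur_sign > 0) max(seg) else min(seg)
    )
  }
  for (i in seq_along(accel)) {
    s <- if (accel[i] > 0) 1 else if (accel[i] < 0) -1 else 0
    if (s != cur_sign) {
      flush(i - 1L)
      cur_sign <- s
      cur_start <- i
    }
  }
  flush(length(accel))
  if (!length(events)) {
    return(data.frame(sign = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak = numeric(0)))
  }
  do.call(rbind, events)
}

# Exhaustive search over all one-to-one head/detection matchings with
# distance gating: maximizes cardinality, then minimizes total distance.
# Returns list(cardinality, cost).
oracle_assignment <- function(heads, dets, max_disp) {
  n <- nrow(heads); m <- nrow(dets)
  if (n == 0L || m == 0L) return(list(cardinality = 0L, cost = 0))
  d <- sqrt(outer(heads[, 1], dets[, 1], "-")^2 +
            outer(heads[, 2], dets[, 2], "-")^2)
  best <- list(cardinality = -1L, cost = Inf)
  recurse <- function(i, used, card, cost) {
    if (i > n) {
      if (card > best$cardinality ||
          (card == best$cardinality && cost < best$cost)) {
        best <<- list(cardinality = card, cost = cost)
      }
      return()
    }
    recurse(i + 1L, used, card, cost)  # head i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= max_disp) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

# cardinality and cost of an assignment_step() result
matching_summary <- function(heads, dets, match) {
  hit <- which(!is.na(match))
  if (!length(hit)) return(list(cardinality = 0L, cost = 0))
  d <- sqrt((heads[hit, 1] - dets[match[hit], 1])^2 +
            (heads[hit, 2] - dets[match[hit], 2])^2)
  list(cardinality = length(hit), cost = sum(d))
}

# straight-line track along x whose raw per-interval speeds equal `speeds`
make_straight_track <- function(speeds, dt = 1, track_id = 1L, y = 0) {
  x <- cumsum(c(0, speeds * dt))
  tibble::tibble(
    track_id = track_id,
    frame = seq_along(x),
    time_s = (seq_along(x) - 1) * dt,
    x_mm = x,
    y_mm = y
  )
}

# track tibble from an arbitrary position matrix
make_track <- function(pos, dt = 1, track_id = 1L) {
  tibble::tibble(
    track_id = track_id,
    frame = seq_len(nrow(pos)),
    time_s = (seq_len(nrow(pos)) - 1) * dt,
    x_mm = pos[, 1],
    y_mm = pos[, 2]
  )
}

# parallel-lane dataset: animals on one column heading +x with zero turning,
# so pairwise spacing stays constant for the whole assay
parallel_lane_dataset <- function(n_animals, spacing, seed,
                                  duration_s = 120, dropout_prob = 0,
                                  genotype = genotype_params(
                                    "wt", 0.15, 0.2, 0.023, turn_sd = 0)) {
  arena <- c(60, spacing * (n_animals + 1))
  cfg <- sim_config(n_animals = n_animals, duration_s = duration_s,
                    dropout_prob = dropout_prob, arena_mm = arena,
                    min_spacing_mm = spacing, seed = seed)
  starts <- cbind(x = rep(5, n_animals), y = seq_len(n_animals) * spacing)
  generate_dataset(cfg, genotype, starts = starts, headings = 0)
}
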
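#' Linearly interpolate bridged gaps inside one track
#'
#' Tracks whose 1-2 frame dropouts were bridged by the linker have missing
#' frames; kinematics requires a uniform time step, so missing positions are
#' filled by linear interpolation between the neighbouring observations.
#'
#' @param track tibble with `frame`, `time_s`, `x_mm`, `y_mm` for a single
#'   track, time-ordered.
#' @param dt expected frame interval in seconds.
#' @return The track with every intermediate frame present; an added logical
#'   column `interpolated` marks filled rows.
#' @export
interpolate_gaps <- function(track, dt = 1) {
  stopifnot(nrow(track) >= 2L)
  track <- track[order(track$time_s), ]
  t_full <- seq(track$time_s[1], track$time_s[nrow(track)], by = dt)
  if (length(t_full) == nrow(track)) {
    track$interpolated <- FALSE
    return(track)
  }
  x <- stats::approx(track$time_s, track$x_mm, xout = t_full)$y
  y <- stats::approx(track$time_s, track$y_mm, xout = t_full)$y
  frame0 <- track$frame[1]
  out <- tibble::tibble(
    frame = as.integer(frame0 + round((t_full - t_full[1]) / dt)),
    time_s = t_full, x_mm = x, y_mm = y,
    interpolated = !(round(t_full, 9) %in% round(track$time_s, 9))
  )
  if ("track_id" %in% names(track)) {
    out <- tibble::add_column(out, track_id = track$track_id[1],
                              .before = 1L)
  }
  out
}

#' Per-interval (raw) speed of a track
#'
#' Speed is the path distance travelled between consecutive centroids
#' divided by the time it took: `speed[i] = |p[i+1] - p[i]| / dt`.
#'
#' @param track tibble with `time_s`, `x_mm`, `y_mm`, uniformly sampled
#'   (interpolate bridged gaps first, see [interpolate_gaps()]).
#' @return Numeric vector of nonnegative speeds, length `nrow(track) - 1`.
#' @export
raw_speed <- function(track) {
  stopifnot(nrow(track) >= 2L)
  t <- track$time_s
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("track is not uniformly sampled; interpolate or split it first",
         call. = FALSE)
  }
  sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2) / dts
}

#' Sliding-window mean of a speed series
#'
#' Each reported speed is the mean of `window` consecutive raw speed
#' measurements (a 5-sample window at 1 Hz = a 5 s sliding window), which
#' suppresses centroid-localization noise. Only full windows are emitted,
#' trailing-indexed: `out[i] = mean(raw[i..i+window-1])`.
#'
#' @param raw numeric vector of raw speeds, length >= `window`.
#' @param window window length in samples (default 5).
#' @return Numeric vector of length `length(raw) - window + 1`.
#' @export
smooth_speed <- function(raw, window = 5L) {
  n <- length(raw)
  if (n < window) {
    stop(sprintf("track too short: %d raw speed samples < window of %d",
                 n, window), call. = FALSE)
  }
  cs <- c(0, cumsum(raw))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

#' Instantaneous acceleration from a smoothed speed series
#'
#' First difference over the sampling interval:
#' `accel[i] = (v[i+1] - v[i]) / dt`.
#'
#' @param smooth numeric smoothed speed series (>= 2 samples).
#' @param dt sampling interval in seconds.
#' @return Numeric vector of accelerations, mm/s^2, length
#'   `length(smooth) - 1`.
#' @export
acceleration <- function(smooth, dt = 1) {
  if (length(smooth) < 2L) {
    stop("need at least 2 smoothed samples", call. = FALSE)
  }
  diff(smooth) / dt
}

#' Segment acceleration events at zero crossings
#'
#' An acceleration event is a maximal run of same-sign acceleration: the
#' time elapsed between the acceleration becoming greater (or less) than
#' zero and returning to zero. Exact zeros terminate events and belong to
#' neither sign. Each event carries its duration (run length times `dt`)
#' and signed peak (the extreme value of the run).
#'
#' @param accel numeric acceleration series, mm/s^2.
#' @param dt sampling interval in seconds.
#' @param t0 time of the first acceleration sample (for `start_s`).
#' @return Tibble `sign` (`"+"`/`"-"`), `start_s`, `end_s`, `duration_s`,
#'   `peak`, events ordered by start time; zero rows for an empty or
#'   all-zero series.
#' @export
#' @examples
#' segment_events(c(0.1, 0.2, -0.1, -0.3, 0.05))
segment_events <- function(accel, dt = 1, t0 = 0) {
  empty <- tibble::tibble(sign = character(0), start_s = numeric(0),
                          end_s = numeric(0), duration_s = numeric(0),
                          peak = numeric(0))
  if (length(accel) == 0L) return(empty)
  s <- sign(accel)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]; vals <- r$values[keep]
  peak <- mapply(function(a, b, v) {
    seg <- accel[a:b]
    if (v > 0) max(seg) else min(seg)
  }, starts, ends, vals)
  tibble::new_tibble(list(
    sign = ifelse(vals > 0, "+", "-"),
    start_s = t0 + (starts - 1L) * dt,
    end_s = t0 + ends * dt,
    duration_s = (ends - starts + 1L) * dt,
    peak = as.numeric(peak)
  ), nrow = length(vals))
}

#' Kinematic summary statistics for one track
#'
#' Computes the standard per-track scalars: average speed and the SD and CV
#' of the within-track (smoothed) speed recordings - the SD being the
#' standard fluctuation-magnitude measure - the root-mean-square of the
#' acceleration series ("total acceleration"), and the mean duration and
#' mean signed peaks of acceleration/deceleration events. Speed statistics
#' use the smoothed series; acceleration is likewise derived from it. The
#' SD uses the sample (n - 1) denominator. Event-based fields are `NA` when
#' a track has no event of that sign; CV is `NA` (undefined) when the
#' average speed is zero.
#'
#' @param track tibble with `time_s`, `x_mm`, `y_mm` (single track); bridged
#'   gaps are interpolated internally.
#' @param window smoothing window in samples (default 5).
#' @param dt frame interval in seconds.
#' @return One-row tibble: `track_id` (if present), `duration_s`,
#'   `n_samples`, `avg_speed`, `speed_sd`, `speed_cv`, `rms_accel`,
#'   `mean_event_duration`, `mean_peak_accel`, `mean_peak_decel`,
#'   `n_events_pos`, `n_events_neg`.
#' @export
track_stats <- function(track, window = 5L, dt = 1) {
  track <- interpolate_gaps(track, dt = dt)
  v_raw <- raw_speed(track)
  v <- smooth_speed(v_raw, window)
  a <- acceleration(v, dt)
  ev <- segment_events(a, dt)
  pos <- ev[ev$sign == "+", ]
  neg <- ev[ev$sign == "-", ]
  avg <- mean(v)
  sdv <- stats::sd(v)
  tibble::new_tibble(list(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_,
    duration_s = max(track$time_s) - min(track$time_s),
    n_samples = length(v),
    avg_speed = avg,
    speed_sd = sdv,
    speed_cv = if (avg > 0) sdv / avg else NA_real_,
    rms_accel = sqrt(mean(a^2)),
    mean_event_duration = if (nrow(ev)) mean(ev$duration_s) else NA_real_,
    mean_peak_accel = if (nrow(pos)) mean(pos$peak) else NA_real_,
    mean_peak_decel = if (nrow(neg)) mean(neg$peak) else NA_real_,
    n_events_pos = nrow(pos),
    n_events_neg = nrow(neg)
  ), nrow = 1L)
}

#' Kinematic summaries for a whole track table
#'
#' Applies [track_stats()] to every track; optionally joins a genotype
#' label per track (e.g. recovered from ground truth or carried in the
#' table).
#'
#' @param tracks tibble with `track_id`, `time_s`, `x_mm`, `y_mm` (and
#'   optionally `genotype`).
#' @inheritParams track_stats
#' @return Tibble with one row per track (see [track_stats()]), plus a
#'   `genotype` column when available.
#' @export
tracks_stats <- function(tracks, window = 5L, dt = 1) {
  stopifnot("track_id" %in% names(tracks))
  pieces <- split(seq_len(nrow(tracks)), tracks$track_id)
  out <- dplyr::bind_rows(lapply(pieces, function(idx) {
    tr <- tracks[idx, ]
    st <- track_stats(tr, window = window, dt = dt)
    if ("genotype" %in% names(tr)) st$genotype <- tr$genotype[1]
    st
  }))
  out[order(out$track_id), ]
}
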
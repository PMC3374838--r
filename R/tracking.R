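#' Assemble per-frame detections into tracks
#'
#' Frame-by-frame linking: each open track is extended to an unclaimed
#' detection within `max_disp` of its head via the gated minimum-cost
#' assignment of [assignment_step()]; detections left unclaimed seed new
#' tracks; tracks not extended for more than `max_gap` consecutive frames
#' are closed. Across a bridged gap the gate scales with the number of
#' elapsed frames (an animal undetected for two frames may have travelled
#' two frames' worth of distance), so gap bridging does not selectively
#' fail for fast animals. Bridged gaps leave missing frames inside a track (the
#' kinematics stage interpolates them). Tracks must contain at least two
#' observations; shorter fragments are returned separately as singletons.
#'
#' @param detections tibble with columns `frame`, `time_s`, `x_mm`, `y_mm`
#'   (e.g. from [detect_stack()] or [generate_dataset()]), time-ordered or
#'   not (sorted internally).
#' @param max_disp maximum per-frame displacement in mm (> 0). The default
#'   0.5 mm at 1 Hz sits comfortably above the ~0.3 mm/s maximum crawling
#'   speed seen on plates.
#' @param max_gap maximum number of consecutive frames a track may go
#'   undetected and still be extended (default 2).
#' @return Tibble `track_id, frame, time_s, x_mm, y_mm`, ordered by track
#'   then frame. Single-observation fragments are attached as the
#'   `"singletons"` attribute (same columns, no `track_id`), so that every
#'   input detection appears either in a track or among the singletons.
#' @export
#' @examples
#' cfg <- sim_config(n_animals = 2, duration_s = 30, dropout_prob = 0,
#'                   seed = 3)
#' ds <- generate_dataset(cfg, genotype_preset("wildtype"))
#' tr <- link_tracks(ds$detections)
#' table(tr$track_id)
link_tracks <- function(detections, max_disp = 0.5, max_gap = 2L) {
  if (max_disp <= 0) stop("`max_disp` must be positive", call. = FALSE)
  need <- c("frame", "time_s", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(detections))
  if (length(missing_cols)) {
    stop("detections are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  det <- detections[order(detections$frame, detections$y_mm,
                          detections$x_mm), need]
  frames <- sort(unique(det$frame))

  # open track state: parallel vectors
  open_id <- integer(0); open_x <- numeric(0); open_y <- numeric(0)
  open_age <- integer(0); open_last_frame <- integer(0)
  next_id <- 1L
  rows_track <- integer(nrow(det))  # track id per detection row (0 = none yet)

  det_rows_by_frame <- split(seq_len(nrow(det)), det$frame)

  prev_frame <- NULL
  for (f in frames) {
    if (!is.null(prev_frame)) {
      # age heads by the number of frames elapsed, close stale tracks
      gap <- f - prev_frame - 1L
      if (gap > 0L) open_age <- open_age + gap
      keep <- open_age <= max_gap
      open_id <- open_id[keep]; open_x <- open_x[keep]
      open_y <- open_y[keep]; open_age <- open_age[keep]
      open_last_frame <- open_last_frame[keep]
    }
    rows <- det_rows_by_frame[[as.character(f)]]
    dx <- det$x_mm[rows]; dy <- det$y_mm[rows]
    if (length(open_id)) {
      # a head missed for g frames may have moved up to (g + 1) gates
      mt <- assignment_step(cbind(open_x, open_y), cbind(dx, dy),
                            max_disp * (open_age + 1L))
    } else {
      mt <- integer(0)
    }
    claimed <- rep(FALSE, length(rows))
    if (length(mt)) {
      hit <- which(!is.na(mt))
      for (h in hit) {
        j <- mt[h]
        rows_track[rows[j]] <- open_id[h]
        open_x[h] <- dx[j]; open_y[h] <- dy[j]
        open_age[h] <- 0L; open_last_frame[h] <- f
        claimed[j] <- TRUE
      }
      miss <- which(is.na(mt))
      open_age[miss] <- open_age[miss] + 1L
    }
    # unclaimed detections seed new tracks
    for (j in which(!claimed)) {
      rows_track[rows[j]] <- next_id
      open_id <- c(open_id, next_id)
      open_x <- c(open_x, dx[j]); open_y <- c(open_y, dy[j])
      open_age <- c(open_age, 0L); open_last_frame <- c(open_last_frame, f)
      next_id <- next_id + 1L
    }
    # close tracks that just exceeded the gap
    keep <- open_age <= max_gap
    open_id <- open_id[keep]; open_x <- open_x[keep]
    open_y <- open_y[keep]; open_age <- open_age[keep]
    open_last_frame <- open_last_frame[keep]
    prev_frame <- f
  }

  det$track_id <- rows_track
  counts <- table(det$track_id)
  keep_ids <- as.integer(names(counts)[counts >= 2L])
  singles <- det[!(det$track_id %in% keep_ids), need]
  out <- det[det$track_id %in% keep_ids, c("track_id", need)]
  # renumber surviving tracks consecutively in order of first appearance
  first_seen <- unique(out$track_id)
  out$track_id <- match(out$track_id, first_seen)
  out <- out[order(out$track_id, out$frame), ]
  out <- tibble::as_tibble(out)
  attr(out, "singletons") <- tibble::as_tibble(singles)
  out
}

#' Keep only tracks with enough recorded data
#'
#' Analyses of within-track speed variation use only tracks spanning at
#' least `min_duration_s` seconds of recording (default 30 s).
#'
#' @param tracks track tibble from [link_tracks()] or [read_tracks()].
#' @param min_duration_s minimum track time span in seconds (>= 0).
#' @return The qualifying tracks, original order and ids preserved.
#' @export
filter_tracks <- function(tracks, min_duration_s = 30) {
  if (min_duration_s < 0) stop("`min_duration_s` must be >= 0", call. = FALSE)
  if (nrow(tracks) == 0L) return(tracks)
  span <- tapply(tracks$time_s, tracks$track_id,
                 function(t) max(t) - min(t))
  keep_ids <- as.numeric(names(span)[span >= min_duration_s])
  tracks[tracks$track_id %in% keep_ids, ]
}
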
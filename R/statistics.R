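#' Population average speed
#'
#' The average speed of a population is the mean of all instantaneous
#' (smoothed) speed measurements pooled over every track - so longer tracks
#' contribute more samples, by definition.
#'
#' @param tracks track tibble (`track_id`, `time_s`, `x_mm`, `y_mm`).
#' @param window,dt smoothing window (samples) and frame interval (s).
#' @return Mean speed in mm/s.
#' @export
population_average_speed <- function(tracks, window = 5L, dt = 1) {
  v <- pooled_smooth_speeds(tracks, window, dt)
  if (length(v) == 0L) {
    stop("no speed samples: need at least one track long enough to smooth",
         call. = FALSE)
  }
  mean(v)
}

pooled_smooth_speeds <- function(tracks, window = 5L, dt = 1) {
  if (nrow(tracks) == 0L) return(numeric(0))
  pieces <- split(seq_len(nrow(tracks)), tracks$track_id)
  unlist(lapply(pieces, function(idx) {
    tr <- interpolate_gaps(tracks[idx, ], dt = dt)
    smooth_speed(raw_speed(tr), window)
  }), use.names = FALSE)
}

#' Fraction-of-time speed histogram
#'
#' Pools the smoothed instantaneous speeds of all tracks and bins them into
#' uniform half-open bins `[k w, (k+1) w)`, normalized so the fractions sum
#' to one: the fraction of time the population moves at each speed.
#'
#' @param tracks track tibble.
#' @param bin_width bin width in mm/s (default 0.006).
#' @param window,dt smoothing window and frame interval.
#' @return Tibble `bin_lo, bin_hi, fraction` covering bins up to the
#'   fastest observed speed.
#' @export
speed_histogram <- function(tracks, bin_width = 0.006, window = 5L, dt = 1) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  v <- pooled_smooth_speeds(tracks, window, dt)
  if (length(v) == 0L) {
    stop("no speed samples to histogram", call. = FALSE)
  }
  k <- floor(v / bin_width)
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  tibble::tibble(
    bin_lo = (seq_along(counts) - 1L) * bin_width,
    bin_hi = seq_along(counts) * bin_width,
    fraction = counts / length(v)
  )
}

#' Bin track statistics by average speed
#'
#' Tracks are first separated into half-open bins by their average speed
#' (`floor(avg_speed / bin_width)`); within each bin the mean and SEM of a
#' chosen per-track statistic are computed, each track counting as one
#' independent measurement. Populations are kept apart via the `genotype`
#' column when present.
#'
#' @param stats per-track statistics tibble from [tracks_stats()].
#' @param field name of the `stats` column to summarize (e.g. `"speed_sd"`,
#'   `"rms_accel"`, `"mean_event_duration"`, `"mean_peak_accel"`).
#' @param bin_width average-speed bin width in mm/s (default 0.03).
#' @return Tibble `genotype` (if present), `bin`, `bin_lo`, `bin_hi`, `n`,
#'   `mean`, `sem`; `sem` is `NA` for bins holding a single track. Only
#'   occupied bins appear.
#' @export
bin_tracks_by_avg_speed <- function(stats, field = "speed_sd",
                                    bin_width = 0.03) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (!field %in% names(stats)) {
    stop(sprintf("field '%s' not found in stats", field), call. = FALSE)
  }
  df <- tibble::tibble(
    value = stats[[field]],
    bin = floor(stats$avg_speed / bin_width)
  )
  if ("genotype" %in% names(stats)) df$genotype <- stats$genotype
  df <- df[!is.na(df$value), ]
  grp <- if ("genotype" %in% names(df)) c("genotype", "bin") else "bin"
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    n = dplyr::n(),
    mean = mean(.data$value),
    sem = ifelse(dplyr::n() > 1L,
                 stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
    .groups = "drop"
  )
  out$bin_lo <- out$bin * bin_width
  out$bin_hi <- (out$bin + 1L) * bin_width
  cols <- c(intersect("genotype", names(out)),
            "bin", "bin_lo", "bin_hi", "n", "mean", "sem")
  out[order(out$bin), cols]
}

#' Two-way ANOVA for a genotype effect across speed bins
#'
#' Tests whether a per-track statistic differs between genotypes after
#' accounting for average-speed bin: a main-effects linear model
#' `value ~ genotype + bin` fit by least squares on the (generally
#' unbalanced) design, with Type-II sums of squares. No interaction term is
#' included; bins with fewer than `min_bin_n` tracks in total are dropped
#' (no within-cell variance is estimable there).
#'
#' @param stats per-track statistics tibble with a `genotype` column.
#' @param field column of `stats` to analyse.
#' @param bin_width average-speed bin width in mm/s.
#' @param min_bin_n minimum number of tracks for a bin to enter the model
#'   (default 2).
#' @param interaction include a genotype x bin interaction term (default
#'   `FALSE`).
#' @return A list of class `loco_anova`: `table` (tibble with `term`, `F`,
#'   `df`, `df_resid`, `p`), `genotype_F`, `genotype_p`, `n`.
#' @export
two_way_anova <- function(stats, field = "speed_sd", bin_width = 0.03,
                          min_bin_n = 2L, interaction = FALSE) {
  if (!"genotype" %in% names(stats)) {
    stop("`stats` must carry a genotype column", call. = FALSE)
  }
  df <- data.frame(
    value = stats[[field]],
    genotype = factor(stats$genotype),
    bin = factor(floor(stats$avg_speed / bin_width))
  )
  df <- df[!is.na(df$value), ]
  bin_n <- table(df$bin)
  df <- df[df$bin %in% names(bin_n)[bin_n >= min_bin_n], ]
  df <- droplevels(df)
  if (nlevels(df$genotype) < 2L) {
    stop("degenerate design: need at least two genotypes with data",
         call. = FALSE)
  }
  if (nlevels(df$bin) < 2L) {
    stop("degenerate design: need at least two occupied speed bins",
         call. = FALSE)
  }
  form <- if (interaction) value ~ genotype * bin else value ~ genotype + bin
  fit <- stats::lm(form, data = df)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  resid_row <- terms == "Residuals"
  tab <- tibble::tibble(
    term = terms[!resid_row],
    F = a2$`F value`[!resid_row],
    df = a2$Df[!resid_row],
    df_resid = a2$Df[resid_row],
    p = a2$`Pr(>F)`[!resid_row]
  )
  g <- tab$term == "genotype"
  structure(list(table = tab,
                 genotype_F = tab$F[g][1],
                 genotype_p = tab$p[g][1],
                 n = nrow(df)),
            class = "loco_anova")
}

#' @export
print.loco_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type II), n =", x$n, "tracks\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Two-sample t-test between two groups of track statistics
#'
#' Student's (pooled-variance) two-sided t-test by default; Welch's
#' correction available via `welch = TRUE`. The degenerate case of zero
#' variance in both groups is handled by convention: p = 1 when the means
#' are equal, p = 0 when they are separated.
#'
#' @param a,b numeric vectors of per-track values (each of length >= 2).
#' @param welch use the Welch (unequal-variance) form.
#' @return A list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' t_test_tracks(c(0.1, 0.12, 0.09), c(0.2, 0.22, 0.18))
t_test_tracks <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least two values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}
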
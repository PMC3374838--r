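#' @importFrom rlang .data
NULL

fmt_num <- function(x) formatC(x, format = "f", digits = 6)

write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a track table as TSV
#'
#' The tracks TSV (`track_id, frame, time_s, x_mm, y_mm`, tab-separated,
#' 6-decimal mm and s) is the interchange format between the tracking and
#' kinematics stages and the entry point for re-analysing externally
#' produced tracks. Reading sorts by time within `track_id`, so row order
#' in the file does not matter.
#'
#' @param tracks track tibble.
#' @param path file path.
#' @return `write_tracks()` returns the path invisibly; `read_tracks()`
#'   returns a track tibble.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("track_id", "frame", "time_s", "x_mm", "y_mm")
  extra <- intersect("genotype", names(tracks))
  write_tsv_plain(tracks[, c(cols, extra)], path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "time_s", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("tracks file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$track_id, df$time_s), ]
  tibble::as_tibble(df)
}

#' Write an image stack to a multi-page TIFF
#'
#' Frames are rescaled jointly to `[0, 1]` by the stack maximum.
#'
#' @param frames list of intensity matrices.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_stack_tiff <- function(frames, path) {
  mx <- max(1e-12, max(vapply(frames, max, numeric(1))))
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: 1 Hz frames, 5-sample
#' smoothing window, 30 s minimum track duration, standard bin widths
#' (0.006 mm/s for speed histograms, 0.03 mm/s for binned track curves),
#' 0.5 mm linking gate with a 2-frame bridgeable gap. Values you override
#' are flagged `"user"` in the provenance attribute; the rest are
#' `"default"`. Round-trips losslessly through YAML.
#'
#' @param ... overrides of any default field.
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(n_animals = 10, seed = 42)
#' cfg$min_track_s
pipeline_config <- function(...) {
  defaults <- list(
    n_animals = 30L, duration_s = 120, dt = 1,
    arena_mm = c(25, 25), dropout_prob = 0.33, min_spacing_mm = 1,
    mm_per_px = 0.01, n_substeps = 1L,
    genotypes = c("wildtype", "dopamine_deficient"),
    render = FALSE, image_dim = NULL, blob_sigma = 2, threshold = 0.05,
    min_area = 1L,
    max_disp = 0.5, max_gap = 2L,
    window = 5L, min_track_s = 30,
    hist_bin_width = 0.006, curve_bin_width = 0.03, stat_field = "speed_sd",
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  prov <- ifelse(names(defaults) %in% names(over), "user", "default")
  names(prov) <- names(defaults)
  structure(cfg, provenance = prov, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)], path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config` object (for `write_config`).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_fields <- c("n_animals", "n_substeps", "max_gap", "window",
                  "min_area", "seed")
  for (f in intersect(int_fields, names(vals))) {
    vals[[f]] <- as.integer(vals[[f]])
  }
  do.call(pipeline_config, vals)
}

#' Run the full simulate -> detect -> track -> kinematics -> statistics
#' pipeline
#'
#' Generates a synthetic multi-animal dataset, optionally renders and
#' re-detects frames (otherwise the generator's centroid lists feed the
#' tracker directly), links tracks, filters to the minimum duration,
#' computes per-track kinematics, labels each track with the majority
#' ground-truth genotype, and writes every intermediate and summary table
#' as TSV. All randomness derives from `cfg$seed`. Deterministic: the same
#' config yields byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return A run manifest (list): `config`, `seed`, `package_version`,
#'   `n_tracks_linked`, `n_tracks_filtered`, `mean_track_length_s`,
#'   `files` (named vector of paths), `checksums` (md5 per file), plus the
#'   in-memory `tracks`, `stats`, `histogram`, `binned`, and (when two or
#'   more genotypes are present) `anova` objects.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("loco")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genos <- lapply(cfg$genotypes, function(g) {
    if (inherits(g, "genotype_params")) g else genotype_preset(g)
  })
  sim <- sim_config(n_animals = cfg$n_animals, duration_s = cfg$duration_s,
                    dt = cfg$dt, arena_mm = cfg$arena_mm,
                    dropout_prob = cfg$dropout_prob,
                    min_spacing_mm = cfg$min_spacing_mm,
                    mm_per_px = cfg$mm_per_px,
                    n_substeps = cfg$n_substeps, seed = cfg$seed)
  ds <- generate_dataset(sim, genos)

  detections <- ds$detections
  if (isTRUE(cfg$render)) {
    image_dim <- cfg$image_dim
    if (is.null(image_dim)) {
      image_dim <- rev(ceiling(cfg$arena_mm / cfg$mm_per_px)) + 1L
    }
    frames <- render_stack(
      dplyr::semi_join(ds$truth, ds$detections,
                       by = c("frame", "x_mm", "y_mm")),
      image_dim, cfg$mm_per_px, cfg$blob_sigma)
    detections <- detect_stack(frames, cfg$threshold, cfg$min_area,
                               cfg$mm_per_px, cfg$dt)
  }

  tracks <- link_tracks(detections, max_disp = cfg$max_disp,
                        max_gap = cfg$max_gap)
  n_linked <- length(unique(tracks$track_id))
  tracks <- filter_tracks(tracks, cfg$min_track_s)
  if (nrow(tracks) == 0L) {
    stop("no tracks survive the minimum-duration filter; rerun the ",
         "tracking stage with a lower `min_track_s`", call. = FALSE)
  }
  tracks <- label_tracks_by_truth(tracks, ds$truth, cfg$max_disp)

  stats <- tracks_stats(tracks, window = cfg$window, dt = cfg$dt)
  hist <- speed_histogram(tracks, cfg$hist_bin_width, cfg$window, cfg$dt)
  binned <- bin_tracks_by_avg_speed(stats, cfg$stat_field,
                                    cfg$curve_bin_width)
  anova_res <- NULL
  if ("genotype" %in% names(stats) &&
      length(unique(stats$genotype)) >= 2L) {
    anova_res <- tryCatch(
      two_way_anova(stats, cfg$stat_field, cfg$curve_bin_width),
      error = function(e) NULL)
  }

  files <- c(
    truth = file.path(out_dir, "truth.tsv"),
    detections = file.path(out_dir, "detections.tsv"),
    tracks = file.path(out_dir, "tracks.tsv"),
    stats = file.path(out_dir, "track_stats.tsv"),
    histogram = file.path(out_dir, "speed_histogram.tsv"),
    binned = file.path(out_dir, "binned_summary.tsv")
  )
  write_tsv_plain(ds$truth, files["truth"])
  write_tsv_plain(detections, files["detections"])
  write_tracks(tracks, files["tracks"])
  write_tsv_plain(stats, files["stats"])
  write_tsv_plain(hist, files["histogram"])
  write_tsv_plain(binned, files["binned"])

  spans <- tapply(tracks$time_s, tracks$track_id, function(t) max(t) - min(t))
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("locotrack")),
    n_tracks_linked = n_linked,
    n_tracks_filtered = length(unique(tracks$track_id)),
    mean_track_length_s = unname(mean(spans)),
    files = files,
    checksums = tools::md5sum(files),
    tracks = tracks, stats = stats, histogram = hist, binned = binned,
    anova = anova_res
  )
  meta <- manifest[c("seed", "package_version", "n_tracks_linked",
                     "n_tracks_filtered", "mean_track_length_s")]
  meta$checksums <- as.list(manifest$checksums)
  meta$config <- unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)]
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

# label each recovered track with the ground-truth genotype of the nearest
# true animal (majority vote over the track's frames)
label_tracks_by_truth <- function(tracks, truth, max_disp) {
  truth_by_frame <- split(seq_len(nrow(truth)), truth$frame)
  ids <- unique(tracks$track_id)
  lab <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    votes <- character(0)
    for (r in seq_len(nrow(tr))) {
      cand <- truth_by_frame[[as.character(tr$frame[r])]]
      if (is.null(cand)) next
      d2 <- (truth$x_mm[cand] - tr$x_mm[r])^2 +
            (truth$y_mm[cand] - tr$y_mm[r])^2
      j <- which.min(d2)
      if (d2[j] <= max_disp^2) votes <- c(votes, truth$genotype[cand[j]])
    }
    if (!length(votes)) return(NA_character_)
    names(which.max(table(votes)))
  }, character(1))
  tracks$genotype <- lab[match(tracks$track_id, ids)]
  tracks
}
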
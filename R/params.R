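#' Generative parameters for one simulated strain or condition
#'
#' A `genotype_params` object holds the parameters of the stochastic speed
#' process used to simulate one strain: crawling speed is modelled as a
#' mean-reverting diffusion reflected at zero,
#' \deqn{dv = \theta(\mu - v)\,dt + \sigma\,dW,\qquad v \ge 0,}
#' so that the long-run mean speed (`mu_speed`) and the size/volatility of
#' speed fluctuations (`sigma`, `theta`) are independently tunable. The
#' stationary SD of the unreflected process is `sigma / sqrt(2 * theta)`.
#'
#' @param label character, strain/condition label carried through the pipeline.
#' @param mu_speed long-run mean speed, mm/s (must be >= 0).
#' @param theta mean-reversion rate of the speed process, 1/s (must be > 0).
#' @param sigma diffusion coefficient of the speed process, mm/s^1.5 (>= 0).
#' @param turn_sd SD of the per-step heading random walk, radians per step.
#'
#' @return A list of class `genotype_params`.
#' @seealso [genotype_preset()] for ready-made strain-like parameter sets.
#' @export
#' @examples
#' wt <- genotype_params("wt", mu_speed = 0.15, theta = 0.2, sigma = 0.023)
#' stationary_speed_sd(wt)
genotype_params <- function(label, mu_speed, theta, sigma, turn_sd = 0.5) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(mu_speed) || mu_speed < 0) {
    stop("`mu_speed` must be a nonnegative speed in mm/s", call. = FALSE)
  }
  if (!is.numeric(theta) || theta <= 0) {
    stop("`theta` must be a positive rate in 1/s", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma < 0) {
    stop("`sigma` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(turn_sd) || turn_sd < 0) {
    stop("`turn_sd` must be nonnegative", call. = FALSE)
  }
  structure(
    list(label = label, mu_speed = mu_speed, theta = theta,
         sigma = sigma, turn_sd = turn_sd),
    class = "genotype_params"
  )
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf(
    "<genotype_params> %s: mu_speed=%.3f mm/s, theta=%.2f /s, sigma=%.4f, turn_sd=%.2f rad\n  stationary speed SD (unreflected): %.4f mm/s\n",
    x$label, x$mu_speed, x$theta, x$sigma, x$turn_sd, stationary_speed_sd(x)
  ))
  invisible(x)
}

#' Stationary speed SD implied by a parameter set
#'
#' Closed form `sigma / sqrt(2 * theta)` for the unreflected mean-reverting
#' process; a good approximation to the simulated speed SD whenever the
#' reflecting boundary at zero is rarely visited (`mu_speed` more than about
#' two stationary SDs above zero).
#'
#' @param params a [genotype_params()] object.
#' @return Stationary SD in mm/s.
#' @export
stationary_speed_sd <- function(params) {
  params$sigma / sqrt(2 * params$theta)
}

#' Phenomenological strain presets
#'
#' Ready-made parameter sets emulating the qualitative phenotypes of the
#' strains a dopamine-signalling locomotion study compares. The presets are
#' tuned only to reproduce orderings (a dopamine-deficient mutant shows
#' roughly twice the speed-fluctuation SD of wild type; hyperactive variants
#' have a higher mean speed; a slowed variant keeps mutant-sized fluctuations
#' at wild-type mean speed), not any particular strain's exact numbers.
#' Observed crawling speeds on food span roughly 0 to 0.3 mm/s, which
#' constrains `mu_speed` and the fluctuation scale.
#'
#' * `"wildtype"`: mu 0.15 mm/s, stationary speed SD ~0.036 mm/s.
#' * `"dopamine_deficient"`: sigma doubled (speed SD ~0.073 mm/s) and mildly
#'   hyperactive (mu 0.18 mm/s).
#' * `"dopamine_deficient_slowed"`: mutant-sized fluctuations at wild-type
#'   mean speed - dissociates average speed from fluctuation size.
#' * `"dopamine_pretreated"`: wild-type-like parameters (exogenous-dopamine
#'   rescue represented purely as a parameter preset).
#'
#' @param name preset name (see above).
#' @return A [genotype_params()] object.
#' @export
#' @examples
#' genotype_preset("dopamine_deficient")
genotype_preset <- function(name = c("wildtype", "dopamine_deficient",
                                     "dopamine_deficient_slowed",
                                     "dopamine_pretreated")) {
  name <- match.arg(name)
  switch(name,
    wildtype =
      genotype_params("wildtype", mu_speed = 0.15, theta = 0.2,
                      sigma = 0.023, turn_sd = 0.5),
    dopamine_deficient =
      genotype_params("dopamine_deficient", mu_speed = 0.18, theta = 0.2,
                      sigma = 0.046, turn_sd = 0.5),
    dopamine_deficient_slowed =
      genotype_params("dopamine_deficient_slowed", mu_speed = 0.15,
                      theta = 0.2, sigma = 0.046, turn_sd = 0.5),
    dopamine_pretreated =
      genotype_params("dopamine_pretreated", mu_speed = 0.15, theta = 0.2,
                      sigma = 0.023, turn_sd = 0.5)
  )
}

#' Simulation configuration
#'
#' Assay-level settings for the synthetic dataset generator. Defaults mirror
#' a standard plate assay: 2-minute recordings sampled at 1 Hz.
#'
#' `dropout_prob` is the per-frame, per-animal probability that a centroid
#' goes undetected. It stands in for every cause of track fragmentation in a
#' real recording (missed detections, animals touching and merging into one
#' blob, plate-edge excursions). The default 0.33, combined with the
#' tracker's `max_gap = 2` bridging, yields a mean filtered track length of
#' roughly 53 s in a 120 s assay, matching the fragmentation level typical
#' of multi-worm recordings.
#'
#' @param n_animals number of animals in the arena (>= 1).
#' @param duration_s assay length in seconds (default 120).
#' @param dt observation interval in seconds (default 1, i.e. 1 Hz imaging);
#'   `duration_s / dt` must be a whole number of frames.
#' @param arena_mm numeric length-2, arena width and height in mm.
#' @param dropout_prob per-frame per-animal detection dropout probability,
#'   in `[0, 1)`.
#' @param min_spacing_mm minimum initial spacing between animals (grid
#'   placement); an error is raised if the arena cannot hold `n_animals` at
#'   this spacing.
#' @param mm_per_px image calibration used when rendering frames (mm per
#'   pixel, default 0.01).
#' @param n_substeps internal Euler steps per observation interval (>= 1).
#'   The process can be integrated on a finer grid than the camera rate;
#'   observations are subsampled.
#' @param seed integer root seed; all randomness in the generator derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals, duration_s = 120, dt = 1,
                       arena_mm = c(10, 10), dropout_prob = 0.33,
                       min_spacing_mm = 1, mm_per_px = 0.01,
                       n_substeps = 1L, seed = 1L) {
  stopifnot(n_animals >= 1, length(arena_mm) == 2L, all(arena_mm > 0))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n_frames <- duration_s / dt
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("`duration_s / dt` must be a whole number of frames", call. = FALSE)
  }
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("`dropout_prob` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(n_substeps >= 1)
  structure(
    list(n_animals = as.integer(n_animals), duration_s = duration_s, dt = dt,
         arena_mm = arena_mm, dropout_prob = dropout_prob,
         min_spacing_mm = min_spacing_mm, mm_per_px = mm_per_px,
         n_substeps = as.integer(n_substeps), seed = as.integer(seed)),
    class = "sim_config"
  )
}
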
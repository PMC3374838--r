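#' Simulate a speed trace from a mean-reverting process reflected at zero
#'
#' Samples \eqn{dv = \theta(\mu - v)dt + \sigma dW} using the exact Gaussian
#' transition density of the Ornstein-Uhlenbeck process (so the marginal law
#' is unbiased at any step size, unlike an Euler scheme) and reflects at
#' zero by taking the absolute value after each step, keeping speeds
#' nonnegative. With `sigma = 0` the trace relaxes deterministically to
#' `mu_speed`; with noise, the long-run mean approaches `mu_speed` and the
#' long-run SD approaches `sigma / sqrt(2 * theta)` whenever the reflecting
#' boundary is rarely active.
#'
#' @param params a [genotype_params()] object.
#' @param n_steps number of samples to return (>= 2).
#' @param dt time step in seconds.
#' @param seed integer seed; the trace is reproducible for a fixed seed and
#'   the caller's RNG state is left untouched.
#' @param v0 starting speed (mm/s); defaults to `mu_speed`.
#' @return Numeric vector of `n_steps` nonnegative speeds in mm/s.
#' @export
#' @examples
#' wt <- genotype_preset("wildtype")
#' v <- simulate_speed_trace(wt, n_steps = 120, dt = 1, seed = 7)
#' c(mean = mean(v), sd = sd(v))
simulate_speed_trace <- function(params, n_steps, dt, seed, v0 = NULL) {
  stopifnot(inherits(params, "genotype_params"))
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_steps < 2) stop("`n_steps` must be at least 2", call. = FALSE)
  if (is.null(v0)) v0 <- params$mu_speed
  if (v0 < 0) stop("starting speed must be nonnegative", call. = FALSE)
  n_steps <- as.integer(n_steps)
  withr::with_seed(as.integer(seed), {
    a <- exp(-params$theta * dt)
    step_sd <- params$sigma * sqrt((1 - a^2) / (2 * params$theta))
    noise <- step_sd * stats::rnorm(n_steps - 1L)
    mu <- params$mu_speed
    v <- numeric(n_steps)
    v[1L] <- v0
    for (i in seq_len(n_steps - 1L)) {
      v[i + 1L] <- abs(mu + (v[i] - mu) * a + noise[i])
    }
    v
  })
}

#' Simulate a 2-D trajectory from a speed trace
#'
#' Moves a point through the arena at the given per-step speeds while the
#' heading performs a Gaussian random walk with SD `turn_sd` per step. Each
#' displacement has magnitude `speed * dt` before boundary handling; at the
#' arena walls the path is reflected (mirror position, flip heading), which
#' keeps full-assay tracks in-frame the way a physical plate does.
#'
#' @param speed numeric vector of nonnegative per-interval speeds (mm/s);
#'   `speed[i]` covers the interval from position `i` to position `i + 1`.
#' @param turn_sd heading random-walk SD, radians per step.
#' @param start numeric length-2 starting position (mm), inside the arena.
#' @param arena_mm numeric length-2 arena size (mm).
#' @param dt step duration, seconds.
#' @param seed integer seed for the heading walk.
#' @param heading0 initial heading in radians; drawn uniformly if `NULL`.
#' @return A numeric matrix with `length(speed) + 1` rows and columns
#'   `x`, `y` (mm).
#' @export
simulate_trajectory <- function(speed, turn_sd, start, arena_mm, dt = 1,
                                seed = 1L, heading0 = NULL) {
  if (any(speed < 0)) stop("speeds must be nonnegative", call. = FALSE)
  stopifnot(length(start) == 2L, length(arena_mm) == 2L)
  if (any(start < 0) || any(start > arena_mm)) {
    stop("`start` must lie inside the arena", call. = FALSE)
  }
  n <- length(speed)
  withr::with_seed(as.integer(seed), {
    if (is.null(heading0)) heading0 <- stats::runif(1, 0, 2 * pi)
    turns <- if (turn_sd > 0) stats::rnorm(n, sd = turn_sd) else numeric(n)
    heading <- heading0 + cumsum(c(0, turns[-n]))
    pos <- matrix(NA_real_, nrow = n + 1L, ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
    pos[1L, ] <- start
    for (i in seq_len(n)) {
      step <- speed[i] * dt * c(cos(heading[i]), sin(heading[i]))
      p <- pos[i, ] + step
      # reflect off walls (a step never exceeds ~0.5 mm so one fold per axis
      # suffices; loop guards pathological speeds)
      for (ax in 1:2) {
        while (p[ax] < 0 || p[ax] > arena_mm[ax]) {
          if (p[ax] < 0) {
            p[ax] <- -p[ax]
            heading[i:n] <- if (ax == 1L) pi - heading[i:n] else -heading[i:n]
          } else {
            p[ax] <- 2 * arena_mm[ax] - p[ax]
            heading[i:n] <- if (ax == 1L) pi - heading[i:n] else -heading[i:n]
          }
        }
      }
      pos[i + 1L, ] <- p
    }
    pos
  })
}

#' Generate a synthetic multi-animal dataset with ground truth
#'
#' Simulates `n_animals` independent trajectories (genotypes assigned
#' round-robin from `genotypes`), applies per-frame detection dropout, and
#' returns both the surviving per-frame centroid detections - what a blob
#' detector would see - and the full ground truth with identities and true
#' speeds. The speed process is integrated on `n_substeps` internal Euler
#' steps per observation interval and subsampled to the camera rate; the
#' trajectory is stepped at the observation rate so per-frame displacement
#' equals the (average) true speed times `dt`.
#'
#' Initial positions sit on a grid with spacing `min_spacing_mm` (overridable
#' via `starts`); headings are uniform random unless `headings` is given.
#'
#' @param config a [sim_config()] object.
#' @param genotypes a list of [genotype_params()] objects (a single object is
#'   accepted).
#' @param starts optional `n_animals` x 2 matrix of starting positions (mm).
#' @param headings optional numeric vector of initial headings (radians),
#'   recycled to `n_animals`.
#' @return A list with elements
#'   * `detections`: tibble `frame, time_s, x_mm, y_mm` of surviving
#'     detections, sorted by frame then (y, x);
#'   * `truth`: tibble `frame, time_s, animal_id, genotype, x_mm, y_mm,
#'     true_speed_mm_s` (speed over the interval starting at that frame; `NA`
#'     on the final frame);
#'   * `config`: the configuration used.
#' @export
#' @examples
#' cfg <- sim_config(n_animals = 3, duration_s = 20, dropout_prob = 0, seed = 1)
#' ds <- generate_dataset(cfg, genotype_preset("wildtype"))
#' head(ds$truth)
generate_dataset <- function(config, genotypes, starts = NULL,
                             headings = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(genotypes, "genotype_params")) genotypes <- list(genotypes)
  stopifnot(length(genotypes) >= 1L,
            all(vapply(genotypes, inherits, TRUE, "genotype_params")))
  n <- config$n_animals
  n_frames <- as.integer(round(config$duration_s / config$dt)) + 1L

  if (is.null(starts)) {
    starts <- grid_starts(n, config$arena_mm, config$min_spacing_mm)
  } else {
    starts <- as.matrix(starts)
    stopifnot(nrow(starts) == n, ncol(starts) == 2L)
    if (any(starts < 0) || any(sweep(starts, 2, config$arena_mm) > 0)) {
      stop("`starts` must lie inside the arena", call. = FALSE)
    }
  }

  geno_idx <- ((seq_len(n) - 1L) %% length(genotypes)) + 1L
  sub <- config$n_substeps
  dt_fine <- config$dt / sub

  truth_list <- withr::with_seed(config$seed, {
    animal_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    h0 <- if (is.null(headings)) stats::runif(n, 0, 2 * pi) else
      rep_len(headings, n)
    keep <- matrix(stats::runif(n * n_frames) >= config$dropout_prob,
                   nrow = n_frames, ncol = n)
    lapply(seq_len(n), function(i) {
      gp <- genotypes[[geno_idx[i]]]
      v_fine <- simulate_speed_trace(gp, n_steps = (n_frames - 1L) * sub + 1L,
                                     dt = dt_fine, seed = animal_seeds[2L * i - 1L])
      # average fine-step speed over each observation interval: the distance
      # actually covered per frame divided by dt
      v_obs <- colMeans(matrix(v_fine[-length(v_fine)], nrow = sub))
      pos <- simulate_trajectory(v_obs, gp$turn_sd, starts[i, ],
                                 config$arena_mm, dt = config$dt,
                                 seed = animal_seeds[2L * i],
                                 heading0 = h0[i])
      tibble::tibble(
        frame = seq_len(n_frames),
        time_s = (seq_len(n_frames) - 1) * config$dt,
        animal_id = i,
        genotype = gp$label,
        x_mm = pos[, "x"],
        y_mm = pos[, "y"],
        true_speed_mm_s = c(v_obs, NA_real_),
        detected = keep[, i]
      )
    })
  })

  truth <- dplyr::bind_rows(truth_list)
  detections <- truth[truth$detected,
                      c("frame", "time_s", "x_mm", "y_mm")]
  detections <- detections[order(detections$frame, detections$y_mm,
                                 detections$x_mm), ]
  truth$detected <- NULL
  list(detections = tibble::as_tibble(detections), truth = truth,
       config = config)
}

# deterministic grid placement with guaranteed spacing
grid_starts <- function(n, arena_mm, spacing) {
  nx <- floor(arena_mm[1] / spacing)
  ny <- floor(arena_mm[2] / spacing)
  if (nx * ny < n) {
    stop(sprintf(
      "arena %.1f x %.1f mm too small for %d animals at %.2f mm spacing",
      arena_mm[1], arena_mm[2], n, spacing), call. = FALSE)
  }
  ix <- (seq_len(n) - 1L) %% nx
  iy <- (seq_len(n) - 1L) %/% nx
  cbind(x = (ix + 0.5) * spacing, y = (iy + 0.5) * spacing)
}

#' Render one dark-field-style frame
#'
#' Draws each animal as a bright isotropic Gaussian blob on a dark
#' background, emulating dark-field illumination in which worms appear as
#' bright objects. Positions are in mm and converted to pixels with
#' `mm_per_px`; the continuous pixel coordinate of mm position `u` is
#' `u / mm_per_px + 0.5`, i.e. mm 0 is the outer edge of pixel 1.
#'
#' @param positions matrix (or length-2 vector) of animal positions, mm.
#' @param image_dim integer length-2: image height and width in pixels.
#' @param mm_per_px calibration, mm per pixel.
#' @param blob_sigma Gaussian blob SD in pixels.
#' @param intensity peak intensity per blob.
#' @param background constant background level.
#' @return Numeric `image_dim[1]` x `image_dim[2]` matrix; rows are y,
#'   columns are x.
#' @export
render_frame <- function(positions, image_dim, mm_per_px = 0.01,
                         blob_sigma = 2, intensity = 1, background = 0) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  img <- matrix(background, nrow = image_dim[1], ncol = image_dim[2])
  if (nrow(positions) == 0L) return(img)
  px <- positions[, 1] / mm_per_px + 0.5
  py <- positions[, 2] / mm_per_px + 0.5
  if (any(px < 0.5) || any(px > image_dim[2] + 0.5) ||
      any(py < 0.5) || any(py > image_dim[1] + 0.5)) {
    stop("positions fall outside the image after mm -> pixel calibration",
         call. = FALSE)
  }
  half <- ceiling(4 * blob_sigma)
  for (k in seq_len(nrow(positions))) {
    cx <- round(px[k]); cy <- round(py[k])
    xs <- max(1, cx - half):min(image_dim[2], cx + half)
    ys <- max(1, cy - half):min(image_dim[1], cy + half)
    gx <- exp(-((xs - px[k])^2) / (2 * blob_sigma^2))
    gy <- exp(-((ys - py[k])^2) / (2 * blob_sigma^2))
    img[ys, xs] <- img[ys, xs] + intensity * outer(gy, gx)
  }
  img
}

#' Render a whole dataset as an image stack
#'
#' @param truth the `truth` tibble from [generate_dataset()] (only detected
#'   positions should be passed if dropout is to be reflected in the frames).
#' @param image_dim integer length-2 pixel dimensions.
#' @inheritParams render_frame
#' @return A list of frames (matrices), one per frame index present.
#' @export
render_stack <- function(truth, image_dim, mm_per_px = 0.01, blob_sigma = 2,
                         intensity = 1, background = 0) {
  frames <- sort(unique(truth$frame))
  lapply(frames, function(f) {
    sub <- truth[truth$frame == f, , drop = FALSE]
    render_frame(cbind(sub$x_mm, sub$y_mm), image_dim, mm_per_px,
                 blob_sigma, intensity, background)
  })
}
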
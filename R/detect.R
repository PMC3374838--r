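#' Label 8-connected components of a binary mask
#'
#' Two-pass labeling with union-find over the four causal neighbours
#' (left, upper-left, up, upper-right), i.e. full 8-connectivity, which is
#' robust to the thin diagonal joins worm-shaped blobs produce.
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster order of first appearance.
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (x in seq_len(nc)) {
    for (y in seq_len(nr)) {
      if (!mask[y, x]) next
      nb <- integer(0)
      if (y > 1L && lab[y - 1L, x] > 0L) nb <- c(nb, lab[y - 1L, x])
      if (x > 1L) {
        if (lab[y, x - 1L] > 0L) nb <- c(nb, lab[y, x - 1L])
        if (y > 1L && lab[y - 1L, x - 1L] > 0L) nb <- c(nb, lab[y - 1L, x - 1L])
        if (y < nr && lab[y + 1L, x - 1L] > 0L) nb <- c(nb, lab[y + 1L, x - 1L])
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r <- min(roots)
        lab[y, x] <- r
        for (q in roots) parent[q] <- r
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    # renumber components in raster order of their first pixel
    relabel <- integer(nxt)
    seen <- integer(0)
    k <- 0L
    idx <- which(lab > 0L)
    for (i in idx[order(idx)]) {
      r <- roots[lab[i]]
      if (relabel[r] == 0L) {
        k <- k + 1L
        relabel[r] <- k
      }
    }
    lab[idx] <- relabel[roots[lab[idx]]]
  }
  lab
}

#' Detect animal centroids in one intensity image
#'
#' Thresholds the image, labels 8-connected supra-threshold components,
#' discards components smaller than `min_area` pixels, and reports each
#' surviving component's intensity-weighted centre of mass (sub-pixel
#' centroid) and pixel area. Output rows are sorted by (y, x) so the result
#' is independent of component discovery order.
#'
#' @param image 2-D nonnegative intensity matrix (rows = y, columns = x).
#' @param threshold intensity threshold; pixels strictly above it are
#'   foreground.
#' @param min_area minimum component size in pixels (default 1).
#' @return Tibble with columns `x_px`, `y_px` (continuous pixel
#'   coordinates), `area_px`. Empty (zero-row) if nothing is detected.
#' @export
#' @examples
#' img <- render_frame(c(0.5, 0.8), image_dim = c(120, 120))
#' detect_centroids(img, threshold = 0.05)
detect_centroids <- function(image, threshold, min_area = 1) {
  if (!is.matrix(image)) stop("`image` must be a 2-D matrix", call. = FALSE)
  if (any(image < 0)) stop("`image` must be nonnegative", call. = FALSE)
  lab <- label_components(image > threshold)
  n_comp <- max(lab)
  empty <- tibble::tibble(x_px = numeric(0), y_px = numeric(0),
                          area_px = integer(0))
  if (n_comp == 0L) return(empty)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  w <- image[idx]
  ys <- ((idx - 1L) %% nrow(image)) + 1L
  xs <- ((idx - 1L) %/% nrow(image)) + 1L
  area <- tabulate(comp, n_comp)
  wsum <- vapply(seq_len(n_comp), function(k) sum(w[comp == k]), numeric(1))
  cx <- vapply(seq_len(n_comp), function(k) {
    s <- comp == k; sum(w[s] * xs[s])
  }, numeric(1)) / wsum
  cy <- vapply(seq_len(n_comp), function(k) {
    s <- comp == k; sum(w[s] * ys[s])
  }, numeric(1)) / wsum
  keep <- area >= min_area
  if (!any(keep)) return(empty)
  out <- tibble::tibble(x_px = cx[keep], y_px = cy[keep],
                        area_px = as.integer(area[keep]))
  out[order(out$y_px, out$x_px), ]
}

#' Detect centroids across an image stack
#'
#' Applies [detect_centroids()] to every frame and converts pixel
#' coordinates to mm using the same calibration convention as
#' [render_frame()] (`mm = (px - 0.5) * mm_per_px`).
#'
#' @param frames list of same-shaped intensity matrices, in time order.
#' @param threshold,min_area passed to [detect_centroids()].
#' @param mm_per_px calibration, mm per pixel.
#' @param dt frame interval in seconds (for the `time_s` column).
#' @return Tibble `frame, time_s, x_mm, y_mm, area_px`, frame index strictly
#'   increasing; per-frame rows sorted by (y, x).
#' @export
detect_stack <- function(frames, threshold, min_area = 1, mm_per_px = 0.01,
                         dt = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("all frames must share the same shape", call. = FALSE)
  }
  per_frame <- lapply(seq_along(frames), function(i) {
    d <- detect_centroids(frames[[i]], threshold, min_area)
    tibble::tibble(frame = i, time_s = (i - 1) * dt,
                   x_mm = (d$x_px - 0.5) * mm_per_px,
                   y_mm = (d$y_px - 0.5) * mm_per_px,
                   area_px = d$area_px)
  })
  dplyr::bind_rows(per_frame)
}
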
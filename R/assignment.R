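# Minimum-cost bipartite assignment (Hungarian algorithm, shortest
# augmenting paths with potentials, O(n^3)). `cost` is an n x m matrix,
# n <= m is not required; Inf marks forbidden pairs. Returns for each row
# the assigned column (NA_integer_ if unassigned). The matching maximizes
# the number of finite-cost pairs first, then minimizes their total cost.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  # pad to square; replace Inf by a big finite cost so that using a
  # forbidden/dummy pair is always worse than any set of real pairs
  k <- max(n, m)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(finite) + max(finite, 1) + 1 else 1
  cm <- matrix(big, k, k)
  cm[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)

  u <- numeric(k + 1L); v <- numeric(k + 1L)
  p <- integer(k + 1L)          # p[j]: row matched to column j (0 = none)
  way <- integer(k + 1L)
  for (i in seq_len(k)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, k)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(k)) {
        if (used[j + 1L]) next
        cur <- cm[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:k) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- rep(NA_integer_, n)
  for (j in seq_len(k)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= n && j <= m && is.finite(cost[i, j])) {
      match_col[i] <- j
    }
  }
  match_col
}

#' One frame-linking iteration: match open track heads to detections
#'
#' Solves the gated minimum-total-distance one-to-one assignment between the
#' current track head positions and the detections of one frame. Pairs
#' farther apart than `max_disp` are inadmissible; among admissible pairs
#' the matching has maximum cardinality and, among those, minimum total
#' Euclidean distance - a deterministic, order-independent alternative to
#' greedy nearest-neighbour linking that coincides with it when animals are
#' well separated. For speed the admissibility graph is first decomposed
#' into connected components (gating), and the assignment is solved exactly
#' within each component; distance ties are broken toward lower head then
#' detection index.
#'
#' @param heads numeric matrix (n x 2) of open track head positions, mm.
#' @param detections numeric matrix (m x 2) of detection positions, mm.
#' @param max_disp gating radius in mm (> 0); either a scalar or one value
#'   per head (a head whose last detection is `g` frames old is allowed
#'   `g` times the per-frame radius, since the animal kept moving).
#' @return Integer vector of length `n`: for each head the matched detection
#'   row index, or `NA` if unmatched.
#' @export
assignment_step <- function(heads, detections, max_disp) {
  if (any(max_disp <= 0)) stop("`max_disp` must be positive", call. = FALSE)
  if (is.null(dim(heads))) heads <- matrix(heads, ncol = 2L)
  if (is.null(dim(detections))) detections <- matrix(detections, ncol = 2L)
  n <- nrow(heads); m <- nrow(detections)
  match <- rep(NA_integer_, n)
  if (n == 0L || m == 0L) return(match)
  gate <- rep_len(max_disp, n)

  d <- sqrt(outer(heads[, 1], detections[, 1], "-")^2 +
            outer(heads[, 2], detections[, 2], "-")^2)
  adm <- d <= gate  # row-wise recycling: gate[i] applies to head i
  if (!any(adm)) return(match)
  # deterministic tie-break: nudge costs by a sub-resolution lexicographic
  # term favouring lower (head, detection) indices
  eps <- max(gate) * 1e-9
  tie <- outer(seq_len(n), seq_len(m), function(i, j) i * (m + 1) + j) * eps
  cost <- ifelse(adm, d + tie, Inf)

  # connected components of the admissibility graph
  head_comp <- integer(n); det_comp <- integer(m)
  comp <- 0L
  for (s in seq_len(n)) {
    if (head_comp[s] != 0L || !any(adm[s, ])) next
    comp <- comp + 1L
    qh <- s
    while (length(qh)) {
      h <- qh[1L]; qh <- qh[-1L]
      if (head_comp[h] != 0L) next
      head_comp[h] <- comp
      for (j in which(adm[h, ] & det_comp == 0L)) {
        det_comp[j] <- comp
        more <- which(adm[, j] & head_comp == 0L)
        qh <- c(qh, more)
      }
    }
  }
  for (cc in seq_len(comp)) {
    hi <- which(head_comp == cc)
    di <- which(det_comp == cc)
    if (length(hi) == 1L && length(di) == 1L) {
      match[hi] <- di
    } else {
      sub <- hungarian(cost[hi, di, drop = FALSE])
      match[hi] <- di[sub]
    }
  }
  match
}
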
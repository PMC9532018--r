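# One-to-one spike matching and the linear assignment solver.

# Greedy two-pointer matching of two sorted spike time vectors under an
# inclusive window |dt| <= delta. Matching each ground-truth spike to the
# earliest unused compatible sorted spike yields a maximum one-to-one
# matching for interval compatibility on a line (verified against brute-force
# bipartite search in the tests). Returns integer indices into `b` for each
# element of `a` (NA if unmatched). A 1 ps slop keeps the inclusive window
# boundary robust to floating-point representation of spike times.
match_sorted_times <- function(a, b, delta) {
  delta <- delta + 1e-12
  na <- length(a)
  nb <- length(b)
  out <- rep(NA_integer_, na)
  i <- 1L
  j <- 1L
  while (i <= na && j <= nb) {
    d <- b[j] - a[i]
    if (d < -delta) {
      j <- j + 1L
    } else if (d > delta) {
      i <- i + 1L
    } else {
      out[i] <- j
      i <- i + 1L
      j <- j + 1L
    }
  }
  out
}

#' Count one-to-one spike matches between two trains
#'
#' Size of a maximum one-to-one pairing between two sorted spike trains in
#' which paired spikes differ by at most `delta_ms` (inclusive); each spike is
#' used at most once.
#'
#' @param gt_train,sorted_train Sorted numeric vectors of spike times (s).
#' @param delta_ms Matching window (ms).
#' @return Integer match count.
#' @examples
#' count_matches(c(0, 0.0003), c(0.00015), delta_ms = 0.4)
#' @export
count_matches <- function(gt_train, sorted_train, delta_ms = 0.4) {
  check_positive(delta_ms, "delta_ms")
  sum(!is.na(match_sorted_times(gt_train, sorted_train, delta_ms / 1000)))
}

# Minimum-cost linear assignment via augmenting-path Kuhn-Munkres (O(n^3)).
# `cost` is n x m with n <= m; returns an integer vector of length n giving
# the assigned column of each row.
solve_lap_min <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
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
  assign <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  }
  assign
}

#' Optimal one-to-one assignment on an agreement matrix
#'
#' Hungarian (Kuhn-Munkres) assignment maximizing the total agreement score
#' between ground-truth and sorted units. Pairs assigned with zero score are
#' discarded, so the result is a partial one-to-one map. Rows are processed in
#' ground-truth index order, which fixes tie-breaking deterministically.
#'
#' @param scores Matrix of agreement scores (`gt x sorted`), or an
#'   `agreement_matrix` from [agreement_scores()].
#' @return A tibble with `gt_unit`, `sorted_unit` (integer row/column
#'   indices) and `score`, one row per accepted match.
#' @export
hungarian_assign <- function(scores) {
  s <- unclass(scores)
  if (is.null(dim(s))) abort_config("`scores` must be a matrix")
  n_gt <- nrow(s)
  n_srt <- ncol(s)
  if (n_gt == 0 || n_srt == 0) {
    return(tibble::tibble(gt_unit = integer(), sorted_unit = integer(),
                          score = numeric()))
  }
  transposed <- n_gt > n_srt
  mat <- if (transposed) t(s) else s
  assign <- solve_lap_min(max(mat) - mat)
  if (transposed) {
    gt <- assign
    srt <- seq_len(nrow(mat))
  } else {
    gt <- seq_len(nrow(mat))
    srt <- assign
  }
  sc <- s[cbind(gt, srt)]
  keep <- sc > 0
  out <- tibble::tibble(
    gt_unit = as.integer(gt[keep]),
    sorted_unit = as.integer(srt[keep]),
    score = sc[keep]
  )
  dplyr::arrange(out, .data$gt_unit)
}
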
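# Histogram of lags tj - ti over bins defined by sorted `edges_s` (seconds);
# bins are left-open, right-closed: (e_k, e_{k+1}].
ccg_counts <- function(ti, tj, edges_s) {
  n_bins <- length(edges_s) - 1L
  if (length(ti) == 0 || length(tj) == 0) {
    return(integer(n_bins))
  }
  # cumulative counts #{tj <= ti + e} summed over ti, then differenced
  cum <- vapply(edges_s, function(e) sum(findInterval(ti + e, tj)), numeric(1))
  as.integer(diff(cum))
}

#' Auto- and cross-correlograms of a spike train set
#'
#' Counts, for every ordered unit pair (i, j), the time differences
#' `t_j - t_i` falling within `[-window_ms, window_ms]`, binned at `bin_ms`
#' (bins are left-open, right-closed). Auto-correlograms sit on the diagonal
#' and exclude the trivial zero-lag self pairs. The correlogram of (j, i) is
#' defined as the lag-mirror of (i, j), so mirror symmetry
#' `counts[i, j, l] == counts[j, i, -l]` holds exactly.
#'
#' @param trains A `spike_trains` tibble (or plain unit_id/time data frame).
#' @param bin_ms Bin width (ms); must divide `2 * window_ms` into an integer
#'   number of bins.
#' @param window_ms Half-window (ms).
#' @param unit_ids Units to include; defaults to all units present.
#' @return A `correlogram_set`: list with `counts` (array
#'   `n_units x n_units x n_bins`), `unit_ids`, `bin_edges_ms`, `bin_ms`,
#'   `window_ms`.
#' @examples
#' st <- generate_independent(2, 5, 30, seed = 1)
#' cg <- compute_correlograms(st, bin_ms = 1, window_ms = 10)
#' dim(cg$counts)
#' @export
compute_correlograms <- function(trains, bin_ms = 1, window_ms = 50, unit_ids = NULL) {
  check_positive(bin_ms, "bin_ms")
  check_positive(window_ms, "window_ms")
  n_bins <- 2 * window_ms / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort_config("`bin_ms` must divide 2 * window_ms into an integer bin count")
  }
  n_bins <- as.integer(round(n_bins))
  edges_ms <- seq(-window_ms, window_ms, length.out = n_bins + 1L)
  edges_s <- edges_ms / 1000

  tl <- train_list(trains, unit_ids)
  n <- length(tl)
  counts <- array(0L, dim = c(n, n, n_bins),
                  dimnames = list(names(tl), names(tl), NULL))

  zero_bin <- which(edges_ms[-length(edges_ms)] < 0 & edges_ms[-1] >= 0)

  for (i in seq_len(n)) {
    for (j in i:n) {
      cc <- ccg_counts(tl[[i]], tl[[j]], edges_s)
      if (i == j) {
        if (length(zero_bin) == 1) cc[zero_bin] <- cc[zero_bin] - length(tl[[i]])
        counts[i, i, ] <- cc
      } else {
        counts[i, j, ] <- cc
        counts[j, i, ] <- rev(cc)
      }
    }
  }
  structure(
    list(
      counts = counts,
      unit_ids = as.integer(names(tl)),
      bin_edges_ms = edges_ms,
      bin_ms = bin_ms,
      window_ms = window_ms
    ),
    class = "correlogram_set"
  )
}

#' @export
print.correlogram_set <- function(x, ...) {
  cat(sprintf(
    "<correlogram_set> %d units, %d bins of %g ms over [-%g, %g] ms\n",
    length(x$unit_ids), length(x$bin_edges_ms) - 1, x$bin_ms,
    x$window_ms, x$window_ms
  ))
  invisible(x)
}

#' @exportS3Method
tidy.correlogram_set <- function(x, ...) {
  n <- length(x$unit_ids)
  nb <- length(x$bin_edges_ms) - 1L
  centers <- (x$bin_edges_ms[-1] + x$bin_edges_ms[-(nb + 1L)]) / 2
  grid <- expand.grid(i = seq_len(n), j = seq_len(n), bin = seq_len(nb))
  tibble::tibble(
    unit_i = x$unit_ids[grid$i],
    unit_j = x$unit_ids[grid$j],
    lag_ms = centers[grid$bin],
    count = as.integer(x$counts[cbind(grid$i, grid$j, grid$bin)])
  )
}
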
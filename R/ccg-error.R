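#' Lag-wise relative error of cross-correlograms
#'
#' For every pair of ground-truth units that (a) are both matched to a sorted
#' unit and (b) have template cosine similarity above `sim_threshold`, the
#' cross-correlogram of the ground-truth pair and that of the corresponding
#' sorted pair are computed on the same lag grid, and the per-lag relative
#' error is `|ccg_gt(l) - ccg_sorted(l)| / baseline`, with the baseline the
#' mean ground-truth count over the whole window (a per-bin division would be
#' unstable for near-empty bins). Errors are then averaged over pairs. Pairs
#' whose ground-truth correlogram is empty (zero baseline) are skipped with a
#' message.
#'
#' @param gt,sorted `spike_trains` tibbles (ground truth and sorter output).
#' @param comparison A `gt_comparison` holding the unit assignment.
#' @param similarity A `similarity_matrix` for the ground-truth units.
#' @param sim_threshold Only pairs with similarity strictly above this value
#'   are included.
#' @param bin_ms,window_ms Correlogram bin width and half-window (ms).
#' @return A `ccg_error_profile` tibble: `lag_ms` (bin center),
#'   `mean_relative_error`, `n_pairs`, with attribute `sim_threshold`.
#' @export
correlogram_relative_error <- function(gt, sorted, comparison, similarity,
                                       sim_threshold = 0.5,
                                       bin_ms = 0.5, window_ms = 10) {
  stopifnot(inherits(comparison, "gt_comparison"))
  if (nrow(comparison$assignment) == 0) {
    abort_config("the comparison has no matched units")
  }
  n_bins <- 2 * window_ms / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort_config("`bin_ms` must divide 2 * window_ms into an integer bin count")
  }
  n_bins <- as.integer(round(n_bins))
  edges_ms <- seq(-window_ms, window_ms, length.out = n_bins + 1)
  centers <- (edges_ms[-1] + edges_ms[-(n_bins + 1)]) / 2
  edges_s <- edges_ms / 1000

  gtl <- train_list(gt)
  srl <- train_list(sorted)
  asg <- comparison$assignment
  matched_gt <- asg$gt_unit
  err_sum <- numeric(n_bins)
  n_pairs <- 0L
  n_skipped <- 0L
  for (a in seq_along(matched_gt)) {
    for (b in seq_along(matched_gt)) {
      if (b <= a) next
      gi <- matched_gt[a]
      gj <- matched_gt[b]
      if (pair_similarity(similarity, gi, gj) <= sim_threshold) next
      cc_gt <- ccg_counts(gtl[[as.character(gi)]], gtl[[as.character(gj)]], edges_s)
      baseline <- mean(cc_gt)
      if (baseline == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      si <- asg$sorted_unit[a]
      sj <- asg$sorted_unit[b]
      cc_srt <- ccg_counts(srl[[as.character(si)]], srl[[as.character(sj)]], edges_s)
      err_sum <- err_sum + abs(cc_gt - cc_srt) / baseline
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_skipped > 0) {
    inform(sprintf("%d pair(s) skipped: empty ground-truth correlogram", n_skipped))
  }
  out <- tibble::tibble(
    lag_ms = centers,
    mean_relative_error = if (n_pairs > 0) err_sum / n_pairs else rep(NA_real_, n_bins),
    n_pairs = n_pairs
  )
  attr(out, "sim_threshold") <- sim_threshold
  attr(out, "bin_ms") <- bin_ms
  attr(out, "window_ms") <- window_ms
  class(out) <- c("ccg_error_profile", class(out))
  out
}
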
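#' Find synchronous spike events in ground truth
#'
#' Two spikes from two distinct units form a synchronous event (a potential
#' spike collision) if their times differ by at most `window_ms` (inclusive).
#' Every cross-unit pair of spikes within the window is emitted exactly once,
#' oriented so `unit_i < unit_j` and `lag_ms = (t_j - t_i) * 1000`.
#'
#' @param gt A `spike_trains` tibble.
#' @param window_ms Synchrony window (ms).
#' @return Tibble with `unit_i`, `unit_j`, `t_i`, `t_j`, `lag_ms`.
#' @examples
#' gt <- as_spike_trains(
#'   data.frame(unit_id = c(1, 2), time = c(0.1, 0.1015)), duration = 1
#' )
#' find_synchronous_events(gt)
#' @export
find_synchronous_events <- function(gt, window_ms = 2) {
  check_positive(window_ms, "window_ms")
  # 1 ps slop: the inclusive boundary must survive floating-point spike times
  w <- window_ms / 1000 + 1e-12
  tl <- train_list(gt)
  ids <- as.integer(names(tl))
  n <- length(tl)
  out <- list()
  for (a in seq_len(n)) {
    ti <- tl[[a]]
    if (length(ti) == 0) next
    for (b in seq_len(n)) {
      if (b <= a) next
      tj <- tl[[b]]
      if (length(tj) == 0) next
      lo <- count_lt(ti - w, tj)   # strictly before the window
      hi <- count_le(ti + w, tj)   # inclusive upper edge
      k <- hi - lo
      has <- k > 0L
      if (!any(has)) next
      i_rep <- rep.int(which(has), k[has])
      j_idx <- sequence(k[has]) + rep.int(lo[has], k[has])
      out[[length(out) + 1L]] <- tibble::tibble(
        unit_i = ids[a], unit_j = ids[b],
        t_i = ti[i_rep], t_j = tj[j_idx]
      )
    }
  }
  ev <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(unit_i = integer(), unit_j = integer(),
                   t_i = numeric(), t_j = numeric())
  }
  ev$lag_ms <- (ev$t_j - ev$t_i) * 1000
  # guard against floating slop at the inclusive boundary
  ev <- ev[abs(ev$lag_ms) <= window_ms + 1e-9, ]
  attr(ev, "window_ms") <- window_ms
  ev
}

# Default lag bin edges: `n_bins` equal bins spanning [-window_ms, window_ms].
lag_bin_edges <- function(n_bins = 11, window_ms = 2) {
  seq(-window_ms, window_ms, length.out = n_bins + 1)
}

# TRUE for each (unit, time) ground-truth spike that was labeled TP.
tp_lookup <- function(gt_labels, units, times) {
  res <- logical(length(units))
  for (u in unique(units)) {
    sel <- units == u
    lab <- gt_labels[gt_labels$unit_id == u, ]
    idx <- match(times[sel], lab$time)
    res[sel] <- !is.na(idx) & lab$label[idx] == "TP"
  }
  res
}

#' Collision recall per lag bin, per ground-truth pair
#'
#' For every pair of units with at least one synchronous event, bins the
#' events by lag into `n_bins` equal bins spanning
#' `[-window_ms, window_ms]` (default 11 bins over +/-2 ms) and computes the
#' collision recall per bin: the fraction of collided ground-truth spikes
#' that the sorter recovered (label TP). Both spikes of an event contribute,
#' each counted at the event's (signed) lag; a spike participating in several
#' events contributes once per event. Bins with no events have `NA` recall
#' rather than a silent 0.
#'
#' @param events Synchronous events from [find_synchronous_events()].
#' @param comparison A `gt_comparison` from [compare_sortings()] against the
#'   same ground truth.
#' @param n_bins Number of lag bins.
#' @param window_ms Lag half-window (ms); events outside it are ignored.
#' @return A `collision_profile` tibble: `unit_i`, `unit_j`, `lag_ms`
#'   (bin center), `n_events`, `n_spikes` (= 2 x events), `n_tp`, `recall`,
#'   with the bin edges as attribute `bin_edges_ms`.
#' @export
collision_recall_by_lag <- function(events, comparison, n_bins = 11, window_ms = 2) {
  stopifnot(inherits(comparison, "gt_comparison"))
  check_positive(n_bins, "n_bins")
  edges <- lag_bin_edges(n_bins, window_ms)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  ev <- events[abs(events$lag_ms) <= window_ms + 1e-9, , drop = FALSE]
  if (nrow(ev) == 0) {
    inform("no synchronous events: returning an empty collision profile")
    out <- tibble::tibble(
      unit_i = integer(), unit_j = integer(), lag_ms = numeric(),
      n_events = integer(), n_spikes = integer(), n_tp = integer(),
      recall = numeric()
    )
    attr(out, "bin_edges_ms") <- edges
    class(out) <- c("collision_profile", class(out))
    return(out)
  }
  bin <- findInterval(ev$lag_ms, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tp_i <- tp_lookup(comparison$gt_labels, ev$unit_i, ev$t_i)
  tp_j <- tp_lookup(comparison$gt_labels, ev$unit_j, ev$t_j)

  df <- tibble::tibble(
    unit_i = ev$unit_i, unit_j = ev$unit_j, bin = bin,
    tp = as.integer(tp_i) + as.integer(tp_j)
  )
  agg <- df |>
    dplyr::group_by(.data$unit_i, .data$unit_j, .data$bin) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      n_tp = sum(.data$tp),
      .groups = "drop"
    )
  # expand to the full bin grid per pair so empty bins are explicit (NA)
  pairs <- dplyr::distinct(agg, .data$unit_i, .data$unit_j)
  grid <- tidyr::crossing(pairs, bin = seq_len(n_bins))
  out <- dplyr::left_join(grid, agg, by = c("unit_i", "unit_j", "bin")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      n_tp = dplyr::coalesce(.data$n_tp, 0L),
      lag_ms = centers[.data$bin],
      n_spikes = 2L * .data$n_events,
      recall = dplyr::if_else(.data$n_spikes > 0, .data$n_tp / .data$n_spikes,
                              NA_real_)
    ) |>
    dplyr::select("unit_i", "unit_j", "bin", "lag_ms", "n_events",
                  "n_spikes", "n_tp", "recall")
  attr(out, "bin_edges_ms") <- edges
  class(out) <- c("collision_profile", class(out))
  out
}

# similarity value for pairs (unit_i, unit_j) from a similarity_matrix
pair_similarity <- function(similarity, unit_i, unit_j) {
  ids <- rownames(similarity)
  similarity[cbind(match(as.character(unit_i), ids),
                   match(as.character(unit_j), ids))]
}

#' Pool per-pair collision profiles by template similarity
#'
#' Assigns every pair to a cosine-similarity bin and computes the
#' event-weighted average recall per (similarity bin, lag bin):
#' `sum(n_tp) / sum(n_spikes)` over the pairs in the bin. Pairs whose
#' similarity falls outside the bin range are dropped with a message; empty
#' similarity bins are omitted.
#'
#' @param profiles A `collision_profile` from [collision_recall_by_lag()].
#' @param similarity A `similarity_matrix` covering all units in `profiles`.
#' @param similarity_bins Increasing vector of similarity bin edges.
#' @return A pooled `collision_profile_pooled` tibble: `sim_lo`, `sim_hi`,
#'   `lag_ms`, `n_events`, `n_spikes`, `n_tp`, `recall`, `n_pairs`.
#' @export
pool_profiles_by_similarity <- function(profiles, similarity,
                                        similarity_bins = seq(-0.4, 1, by = 0.2)) {
  stopifnot(length(similarity_bins) >= 2)
  sim <- pair_similarity(similarity, profiles$unit_i, profiles$unit_j)
  if (anyNA(sim)) abort_config("some pairs have no similarity entry")
  sbin <- findInterval(sim, similarity_bins, rightmost.closed = TRUE)
  inside <- sbin >= 1 & sbin <= length(similarity_bins) - 1
  if (any(!inside)) {
    inform(sprintf(
      "%d profile rows fall outside the similarity bin range and are dropped",
      sum(!inside)
    ))
  }
  df <- profiles[inside, , drop = FALSE]
  sbin <- sbin[inside]
  out <- tibble::tibble(
    sim_bin = sbin,
    pair = paste(df$unit_i, df$unit_j),
    bin = df$bin, lag_ms = df$lag_ms,
    n_events = df$n_events, n_spikes = df$n_spikes, n_tp = df$n_tp
  ) |>
    dplyr::group_by(.data$sim_bin, .data$bin, .data$lag_ms) |>
    dplyr::summarise(
      n_pairs = dplyr::n_distinct(.data$pair),
      n_events = sum(.data$n_events),
      n_spikes = sum(.data$n_spikes),
      n_tp = sum(.data$n_tp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sim_lo = similarity_bins[.data$sim_bin],
      sim_hi = similarity_bins[.data$sim_bin + 1L],
      recall = dplyr::if_else(.data$n_spikes > 0, .data$n_tp / .data$n_spikes,
                              NA_real_)
    ) |>
    dplyr::select("sim_lo", "sim_hi", "bin", "lag_ms", "n_pairs",
                  "n_events", "n_spikes", "n_tp", "recall")
  attr(out, "bin_edges_ms") <- attr(profiles, "bin_edges_ms")
  attr(out, "similarity_bins") <- similarity_bins
  class(out) <- c("collision_profile_pooled", class(out))
  out
}

#' Collision recall as a function of template similarity
#'
#' Integrates the lag-resolved collision recall over all lag bins: per
#' similarity bin, the event-weighted mean recall
#' `sum(n_tp) / sum(n_spikes)` across the full `[-window, window]` lag range.
#'
#' @inheritParams pool_profiles_by_similarity
#' @return Tibble with `sim_lo`, `sim_hi`, `n_pairs`, `n_events`,
#'   `n_spikes`, `n_tp`, `recall`.
#' @export
collision_recall_by_similarity <- function(profiles, similarity,
                                           similarity_bins = seq(-0.4, 1, by = 0.2)) {
  pooled <- if (inherits(profiles, "collision_profile_pooled")) {
    profiles
  } else {
    pool_profiles_by_similarity(profiles, similarity, similarity_bins)
  }
  pooled |>
    dplyr::group_by(.data$sim_lo, .data$sim_hi) |>
    dplyr::summarise(
      n_pairs = max(.data$n_pairs),
      n_events = sum(.data$n_events),
      n_spikes = sum(.data$n_spikes),
      n_tp = sum(.data$n_tp),
      .groups = "drop"
    ) |>
    dplyr::mutate(recall = dplyr::if_else(.data$n_spikes > 0,
                                          .data$n_tp / .data$n_spikes,
                                          NA_real_))
}

#' Symmetrize a pooled collision profile over lag sign
#'
#' Averages bins at +l and -l (event-weighted), producing a profile over
#' absolute lag. The central bin maps to itself.
#'
#' @param pooled A `collision_profile_pooled`.
#' @return Tibble with `sim_lo`, `sim_hi`, `abs_lag_ms`, `n_spikes`, `n_tp`,
#'   `recall`.
#' @export
symmetrize_profile <- function(pooled) {
  pooled |>
    dplyr::mutate(abs_lag_ms = round(abs(.data$lag_ms), 9)) |>
    dplyr::group_by(.data$sim_lo, .data$sim_hi, .data$abs_lag_ms) |>
    dplyr::summarise(
      n_spikes = sum(.data$n_spikes),
      n_tp = sum(.data$n_tp),
      .groups = "drop"
    ) |>
    dplyr::mutate(recall = dplyr::if_else(.data$n_spikes > 0,
                                          .data$n_tp / .data$n_spikes,
                                          NA_real_))
}
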
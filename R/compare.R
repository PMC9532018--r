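#' Agreement scores between ground-truth and sorted spike trains
#'
#' For every pair (i, j) of a ground-truth and a sorted unit, the agreement
#' score is the Jaccard-like overlap
#' `n_matches / (n_gt_i + n_sorted_j - n_matches)` where `n_matches` is the
#' size of the maximum one-to-one pairing of spikes within `delta_ms`
#' (see [count_matches()]). Scores lie in `[0, 1]`, reaching 1 only for a
#' complete one-to-one match. A pair of empty trains scores 0.
#'
#' @param gt,sorted `spike_trains` tibbles (ground truth and sorter output).
#' @param delta_ms Matching window (ms).
#' @return An `agreement_matrix`: numeric matrix `gt x sorted` with unit ids
#'   as dimnames and attributes `n_gt`, `n_sorted`, `delta_ms`.
#' @export
agreement_scores <- function(gt, sorted, delta_ms = 0.4) {
  check_positive(delta_ms, "delta_ms")
  gtl <- train_list(gt)
  srl <- train_list(sorted)
  n_gt <- lengths(gtl)
  n_srt <- lengths(srl)
  scores <- matrix(0, length(gtl), length(srl),
                   dimnames = list(names(gtl), names(srl)))
  delta <- delta_ms / 1000
  for (i in seq_along(gtl)) {
    for (j in seq_along(srl)) {
      if (n_gt[i] == 0 && n_srt[j] == 0) {
        inform("agreement score of two empty trains defined as 0")
        next
      }
      nm <- sum(!is.na(match_sorted_times(gtl[[i]], srl[[j]], delta)))
      scores[i, j] <- nm / (n_gt[i] + n_srt[j] - nm)
    }
  }
  attr(scores, "n_gt") <- n_gt
  attr(scores, "n_sorted") <- n_srt
  attr(scores, "delta_ms") <- delta_ms
  class(scores) <- c("agreement_matrix", class(scores))
  scores
}

#' Label the spikes of a matched train pair
#'
#' Given a ground-truth train and the sorted train it was assigned to,
#' matched spikes are true positives (TP, labeled on both sides), unmatched
#' sorted spikes are false positives (FP) and unmatched ground-truth spikes
#' are false negatives (FN). The labeling uses the same maximum one-to-one
#' matching as [count_matches()], so counts are consistent with the agreement
#' score.
#'
#' @param gt_train,sorted_train Sorted spike time vectors (s).
#' @param delta_ms Matching window (ms).
#' @return List with character vectors `gt` (TP/FN per ground-truth spike)
#'   and `sorted` (TP/FP per sorted spike).
#' @export
label_spikes <- function(gt_train, sorted_train, delta_ms = 0.4) {
  check_positive(delta_ms, "delta_ms")
  m <- match_sorted_times(gt_train, sorted_train, delta_ms / 1000)
  gt_lab <- ifelse(is.na(m), "FN", "TP")
  srt_lab <- rep("FP", length(sorted_train))
  srt_lab[m[!is.na(m)]] <- "TP"
  list(gt = gt_lab, sorted = srt_lab)
}

#' Per-unit performance metrics from spike labels
#'
#' Computes, from the TP/FP/FN labels of one matched pair,
#' `accuracy = TP / (TP + FP + FN)`, `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FN)`. Metrics with an all-zero denominator are 0 with
#' a warning.
#'
#' @param labels Output of [label_spikes()].
#' @return One-row tibble with `n_tp`, `n_fp`, `n_fn`, `accuracy`,
#'   `precision`, `recall`.
#' @export
unit_metrics <- function(labels) {
  tp <- sum(labels$gt == "TP")
  fp <- sum(labels$sorted == "FP")
  fn <- sum(labels$gt == "FN")
  if (tp + fp == 0 || tp + fn == 0) {
    warn("metric denominator is zero; reporting 0")
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    n_tp = tp, n_fp = fp, n_fn = fn,
    accuracy = safe_div(tp, tp + fp + fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn)
  )
}

#' Classify sorted units
#'
#' Applies the standard mutually exclusive sorted-unit classes:
#' * `well_detected` - matched units with accuracy >= 0.8 (inclusive);
#' * `overmerged` - units with an agreement score >= 0.2 with more than one
#'   ground-truth unit;
#' * `redundant` - units that are not the assigned (best) match of any
#'   ground-truth unit but still score >= 0.2 with one;
#' * `false_positive` - unassigned units whose best score is < 0.2;
#' * `other` - everything else (e.g., matched units below 0.8 accuracy).
#'
#' Rules are evaluated in the order listed.
#'
#' @param scores An `agreement_matrix`.
#' @param assignment Assignment tibble from [hungarian_assign()].
#' @param metrics Per-ground-truth-unit metrics tibble containing `gt_unit`
#'   and `accuracy` (as produced by [compare_sortings()]).
#' @return Tibble with `sorted_unit` (column index) and `class`.
#' @export
classify_units <- function(scores, assignment, metrics) {
  s <- unclass(scores)
  n_srt <- ncol(s)
  cls <- character(n_srt)
  for (j in seq_len(n_srt)) {
    col <- s[, j]
    if (length(col) == 0) col <- 0
    matched_gt <- assignment$gt_unit[assignment$sorted_unit == j]
    acc <- if (length(matched_gt) == 1) {
      metrics$accuracy[metrics$gt_unit == matched_gt]
    } else {
      NA_real_
    }
    cls[j] <- if (length(matched_gt) == 1 && isTRUE(acc >= 0.8)) {
      "well_detected"
    } else if (sum(col >= 0.2) > 1) {
      "overmerged"
    } else if (length(matched_gt) == 0 && any(col >= 0.2)) {
      "redundant"
    } else if (length(matched_gt) == 0 && max(col) < 0.2) {
      "false_positive"
    } else {
      "other"
    }
  }
  tibble::tibble(sorted_unit = seq_len(n_srt), class = cls)
}

#' Compare a sorting output against ground truth
#'
#' Runs the full ground-truth comparison: agreement scores for all unit pairs
#' ([agreement_scores()]), Hungarian assignment of sorted to ground-truth
#' units ([hungarian_assign()]), per-spike TP/FP/FN labels for every matched
#' pair ([label_spikes()]), per-unit accuracy/precision/recall
#' ([unit_metrics()]) and sorted-unit classes ([classify_units()]).
#' Ground-truth units left unmatched get zero metrics and all-FN labels;
#' unmatched sorted units get all-FP labels.
#'
#' @param gt,sorted `spike_trains` tibbles.
#' @param delta_ms Matching window (ms).
#' @return A `gt_comparison` object; use [tidy()] for per-unit metrics and
#'   [glance()] for global averages.
#' @examples
#' gt <- generate_independent(3, 5, 20, seed = 1)
#' cmp <- compare_sortings(gt, oracle_sorter(gt))
#' glance(cmp)
#' @export
compare_sortings <- function(gt, sorted, delta_ms = 0.4) {
  scores <- agreement_scores(gt, sorted, delta_ms)
  assignment <- hungarian_assign(scores)
  gtl <- train_list(gt)
  srl <- train_list(sorted)
  gt_ids <- as.integer(names(gtl))
  srt_ids <- as.integer(names(srl))

  gt_labels <- vector("list", length(gtl))
  srt_labels <- setNames(
    lapply(srl, function(tt) rep("FP", length(tt))),
    names(srl)
  )
  metrics <- vector("list", length(gtl))
  for (i in seq_along(gtl)) {
    srt_row <- assignment$sorted_unit[assignment$gt_unit == i]
    if (length(srt_row) == 1) {
      lab <- label_spikes(gtl[[i]], srl[[srt_row]], delta_ms)
      gt_labels[[i]] <- lab$gt
      srt_labels[[srt_row]] <- lab$sorted
      metrics[[i]] <- dplyr::bind_cols(
        tibble::tibble(gt_unit = i, sorted_unit = srt_row, matched = TRUE),
        unit_metrics(lab)
      )
    } else {
      gt_labels[[i]] <- rep("FN", length(gtl[[i]]))
      metrics[[i]] <- tibble::tibble(
        gt_unit = i, sorted_unit = NA_integer_, matched = FALSE,
        n_tp = 0L, n_fp = 0L, n_fn = length(gtl[[i]]),
        accuracy = 0, precision = 0, recall = 0
      )
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  classes <- classify_units(scores, assignment, metrics)

  # map row/column indices to the actual unit ids
  assignment$gt_unit <- gt_ids[assignment$gt_unit]
  assignment$sorted_unit <- srt_ids[assignment$sorted_unit]
  metrics$gt_unit <- gt_ids[metrics$gt_unit]
  metrics$sorted_unit <- srt_ids[metrics$sorted_unit]
  classes$sorted_unit <- srt_ids[classes$sorted_unit]

  gt_label_tbl <- tibble::tibble(
    unit_id = rep(gt_ids, lengths(gt_labels)),
    time = flat_num(gtl),
    label = as.character(unlist(gt_labels, use.names = FALSE))
  )
  srt_label_tbl <- tibble::tibble(
    unit_id = rep(srt_ids, lengths(srt_labels)),
    time = flat_num(srl),
    label = as.character(unlist(srt_labels, use.names = FALSE))
  )

  structure(
    list(
      agreement = scores,
      assignment = assignment,
      gt_labels = gt_label_tbl,
      sorted_labels = srt_label_tbl,
      metrics = metrics,
      classes = classes,
      gt_unit_ids = gt_ids,
      sorted_unit_ids = srt_ids,
      delta_ms = delta_ms
    ),
    class = "gt_comparison"
  )
}

#' @export
print.gt_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<gt_comparison> %d gt units vs %d sorted units (%d matched)\n",
    g$n_gt_units, g$n_sorted_units, g$n_matched
  ))
  cat(sprintf(
    "  accuracy %.3f | precision %.3f | recall %.3f\n",
    g$accuracy, g$precision, g$recall
  ))
  invisible(x)
}

#' @exportS3Method
tidy.gt_comparison <- function(x, ...) {
  dplyr::left_join(
    x$metrics,
    dplyr::rename(x$classes, sorted_class = "class"),
    by = "sorted_unit"
  )
}

#' @exportS3Method
glance.gt_comparison <- function(x, ...) {
  cls <- table(factor(
    x$classes$class,
    levels = c("well_detected", "false_positive", "redundant", "overmerged", "other")
  ))
  tibble::tibble(
    n_gt_units = length(x$gt_unit_ids),
    n_sorted_units = length(x$sorted_unit_ids),
    n_matched = nrow(x$assignment),
    accuracy = mean(x$metrics$accuracy),
    precision = mean(x$metrics$precision),
    recall = mean(x$metrics$recall),
    n_well_detected = as.integer(cls[["well_detected"]]),
    n_false_positive = as.integer(cls[["false_positive"]]),
    n_redundant = as.integer(cls[["redundant"]]),
    n_overmerged = as.integer(cls[["overmerged"]]),
    n_other = as.integer(cls[["other"]])
  )
}

#' Export a comparison as JSON plus a per-spike label table
#'
#' Writes `<path>.json` (assignment, per-unit metrics, sorted-unit classes)
#' and `<path>_labels.tsv` (side, unit_id, time_s, label for both the
#' ground-truth and sorted spikes).
#'
#' @param cmp A `gt_comparison`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  obj <- list(
    delta_ms = cmp$delta_ms,
    assignment = cmp$assignment,
    metrics = cmp$metrics,
    classes = cmp$classes,
    summary = glance(cmp)
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  labels <- dplyr::bind_rows(
    dplyr::mutate(cmp$gt_labels, side = "gt"),
    dplyr::mutate(cmp$sorted_labels, side = "sorted")
  )
  utils::write.table(
    data.frame(
      side = labels$side, unit_id = labels$unit_id,
      time_s = format(labels$time, digits = 17), label = labels$label
    ),
    paste0(path, "_labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
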
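#' Oracle sorter
#'
#' Returns the ground truth itself, re-labeled with fresh consecutive unit
#' ids. Comparing it against the ground truth must give perfect metrics; it
#' anchors the boundary behavior of every comparison metric.
#'
#' @param gt A `spike_trains` tibble.
#' @return A `spike_trains` tibble with identical spike times.
#' @export
oracle_sorter <- function(gt) {
  tl <- train_list(gt)
  df <- tibble::tibble(
    unit_id = rep(seq_along(tl), lengths(tl)),
    time = flat_num(tl)
  )
  as_spike_trains(df, st_duration(gt))
}

#' Specify a controlled degradation of the oracle
#'
#' A `degradation_model` describes how [degraded_oracle()] corrupts the
#' ground truth: a deletion probability for collided spikes (`p_drop`, either
#' a single number or a function of the event lag in ms and the pair's
#' template similarity), a Gaussian timing jitter applied to surviving
#' spikes, and a rate of spurious spikes injected per unit.
#'
#' @param p_drop Number in `[0, 1]` or `function(lag_ms, similarity)`
#'   returning such numbers (vectorized).
#' @param jitter_ms Sd (ms) of the Gaussian jitter applied to every surviving
#'   spike; 0 disables it.
#' @param fp_rate Rate (Hz) of spurious Poisson spikes injected per unit.
#' @param seed Integer seed; the degraded oracle is deterministic under it.
#' @return A `degradation_model` object.
#' @export
degradation_model <- function(p_drop = 0, jitter_ms = 0, fp_rate = 0, seed = 1) {
  if (!is.function(p_drop)) {
    if (!is.numeric(p_drop) || length(p_drop) != 1L || p_drop < 0 || p_drop > 1) {
      abort_config("`p_drop` must be a probability in [0, 1] or a function")
    }
  }
  check_non_negative(jitter_ms, "jitter_ms")
  check_non_negative(fp_rate, "fp_rate")
  structure(
    list(p_drop = p_drop, jitter_ms = jitter_ms, fp_rate = fp_rate,
         seed = as.integer(seed)),
    class = "degradation_model"
  )
}

#' Degrade the oracle in a controlled, collision-targeted way
#'
#' Starts from the ground truth and deletes each *collided* spike (a spike
#' participating in at least one synchronous event) with the model's
#' deletion probability, evaluated at the spike's minimum-|lag| event and, if
#' a similarity matrix is supplied, at that pair's template similarity. Each
#' collided spike receives exactly one Bernoulli draw, so with a constant
#' `p_drop` the expected collision recall is exactly `1 - p_drop` in every
#' lag bin. Surviving spikes are then jittered and spurious spikes injected
#' per the model. The per-spike deletion probabilities actually used are
#' attached as attribute `"deletion_probs"` (a tibble `unit_id`, `time`,
#' `p`), which lets analyses compute exact model-implied expectations.
#'
#' @param gt A `spike_trains` tibble.
#' @param events Synchronous events from [find_synchronous_events()] on `gt`.
#' @param model A [degradation_model()].
#' @param similarity Optional `similarity_matrix` used when `p_drop` is a
#'   function of similarity.
#' @return A `spike_trains` tibble.
#' @export
degraded_oracle <- function(gt, events, model, similarity = NULL) {
  stopifnot(inherits(model, "degradation_model"))
  duration <- st_duration(gt)
  tl <- train_list(gt)
  ids <- as.integer(names(tl))

  # representative event per collided spike: the minimum-|lag| one
  sides <- dplyr::bind_rows(
    tibble::tibble(unit_id = events$unit_i, time = events$t_i,
                   lag_ms = events$lag_ms, other = events$unit_j),
    tibble::tibble(unit_id = events$unit_j, time = events$t_j,
                   lag_ms = events$lag_ms, other = events$unit_i)
  )
  rep_ev <- sides |>
    dplyr::group_by(.data$unit_id, .data$time) |>
    dplyr::slice_min(abs(.data$lag_ms), with_ties = FALSE) |>
    dplyr::ungroup()

  p <- if (is.function(model$p_drop)) {
    sim <- if (is.null(similarity)) {
      rep(NA_real_, nrow(rep_ev))
    } else {
      pair_similarity(similarity, rep_ev$unit_id, rep_ev$other)
    }
    as.numeric(model$p_drop(rep_ev$lag_ms, sim))
  } else {
    rep(model$p_drop, nrow(rep_ev))
  }
  if (any(p < 0 | p > 1)) abort_config("`p_drop` produced values outside [0, 1]")
  probs <- tibble::tibble(unit_id = rep_ev$unit_id, time = rep_ev$time, p = p)

  out <- with_seed(model$seed, {
    drop_draw <- runif(nrow(probs)) < probs$p
    per_unit <- lapply(seq_along(tl), function(a) {
      u <- ids[a]
      tt <- tl[[a]]
      pu <- probs[probs$unit_id == u, ]
      del <- pu$time[drop_draw[probs$unit_id == u]]
      if (length(del)) tt <- tt[!(tt %in% del)]
      if (model$jitter_ms > 0 && length(tt)) {
        tt <- tt + rnorm(length(tt), 0, model$jitter_ms / 1000)
        tt <- pmin(pmax(tt, 0), duration)
      }
      if (model$fp_rate > 0) {
        tt <- c(tt, rpoisson_train(model$fp_rate, duration))
      }
      sort(tt)
    })
    per_unit
  })
  df <- tibble::tibble(
    unit_id = rep(seq_along(tl), lengths(out)),
    time = flat_num(out)
  )
  res <- as_spike_trains(df, duration, seed = model$seed)
  attr(res, "deletion_probs") <- probs
  res
}

#' Greedy template-matching sorter
#'
#' A minimal template-matching spike sorter that operates directly with the
#' true templates (no clustering stage), isolating the matching step that
#' collision resolution depends on. Per 10-s chunk (with margins) it
#' iteratively peels spikes off the traces:
#'
#' 1. detect candidate times where any channel crosses
#'    `-threshold x noise_sd` at a local minimum (noise estimated robustly
#'    per channel via [estimate_noise()]);
#' 2. for every candidate, template and small peak offset, compute the
#'    least-squares amplitude, clamped to `[0.7, 1.3]` (matching the
#'    generator's modulation bounds), and the resulting reduction in residual
#'    squared norm;
#' 3. greedily accept the best non-overlapping reductions, subtract the
#'    scaled templates from the residual, and repeat for up to `max_passes`
#'    passes so that overlapping spikes emerge once their partner has been
#'    peeled away.
#'
#' @param recording A `recording`.
#' @param templates The `template_set` used to build the recording (or any
#'   set with matching channel count and sampling rate).
#' @param threshold Detection threshold in noise-SD multiples.
#' @param max_passes Maximum peeling passes per chunk.
#' @param max_offset Peak alignment offsets explored, in samples.
#' @param amp_bounds Acceptable amplitude range for a match (multiplicative).
#' @param unit_refractory_ms Per-unit refractory period enforced during
#'   matching (ms): a unit is never fitted twice within this distance, so the
#'   residual of a collision must be explained by a different unit. Set to 0
#'   to disable.
#' @return A `spike_trains` tibble of sorted spikes (unit ids follow the
#'   template order); the fitted amplitude is attached as column `amp`.
#' @export
greedy_tm_sorter <- function(recording, templates, threshold = 5,
                             max_passes = 12, max_offset = 2L,
                             amp_bounds = c(0.7, 1.3),
                             unit_refractory_ms = 3) {
  stopifnot(inherits(recording, "recording"), inherits(templates, "template_set"))
  d <- dim(templates$waveforms)
  tlen <- d[2]
  n_ch <- d[3]
  if (n_ch != recording$n_channels) {
    abort_config("template and recording channel counts differ")
  }
  fs <- recording$sampling_rate
  check_positive(threshold, "threshold")
  max_offset <- as.integer(max_offset)

  noise_sd <- estimate_noise(recording)
  thr <- -threshold * pmax(noise_sd, 1e-6)
  peak_idx <- template_peak_index(templates)
  wav <- as.vector(templates$waveforms)

  events <- list()
  cs <- recording$chunk_samples
  margin <- tlen + max_offset + 1L
  n_chunks <- ceiling(recording$n_samples / cs)

  for (ck in seq_len(n_chunks)) {
    core_a <- (ck - 1L) * cs + 1L
    core_b <- min(ck * cs, recording$n_samples)
    fa <- max(1L, core_a - margin)
    fb <- min(recording$n_samples, core_b + margin)
    R <- get_traces(recording, fa, fb)
    ev <- tm_sort_chunk(R, thr, wav, d, as.integer(peak_idx),
                        max_offset, as.integer(max_passes),
                        amp_bounds[1], amp_bounds[2],
                        as.integer(round(0.0005 * fs)),
                        as.integer(round(unit_refractory_ms / 1000 * fs)))
    if (nrow(ev) > 0) {
      abs_sample <- fa - 1L + ev[, 2]
      core <- abs_sample >= core_a & abs_sample <= core_b
      if (any(core)) {
        events[[length(events) + 1L]] <-
          cbind(ev[core, 1], abs_sample[core], ev[core, 3])
      }
    }
  }

  if (length(events) == 0L) {
    res <- as_spike_trains(tibble::tibble(unit_id = integer(), time = numeric()),
                           duration = recording$duration)
    res$amp <- numeric(0)
    return(res)
  }
  em <- do.call(rbind, events)
  df <- tibble::tibble(
    unit_id = as.integer(em[, 1]),
    time = (em[, 2] - 1) / fs,
    amp = em[, 3]
  )
  df <- dplyr::arrange(df, .data$unit_id, .data$time)
  res <- as_spike_trains(df[, c("unit_id", "time")], duration = recording$duration)
  res$amp <- df$amp
  res
}
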
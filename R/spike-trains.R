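#' Spike train tables
#'
#' Spike trains are stored as a tibble with one row per spike: `unit_id`
#' (integer) and `time` (seconds, sorted within unit), carrying the recording
#' `duration` (s) and generation parameters as attributes. `as_spike_trains()`
#' validates and classes a plain data frame in that shape.
#'
#' @param x Data frame with columns `unit_id` and `time`.
#' @param duration Recording duration (s).
#' @param nominal_rate,nominal_correlation,refractory_ms,seed Optional
#'   generation metadata stored as attributes.
#' @return A tibble of class `spike_trains`.
#' @export
as_spike_trains <- function(x, duration,
                            nominal_rate = NA_real_,
                            nominal_correlation = NA_real_,
                            refractory_ms = NA_real_,
                            seed = NA_integer_) {
  stopifnot(all(c("unit_id", "time") %in% names(x)))
  check_non_negative(duration, "duration")
  out <- tibble::tibble(
    unit_id = as.integer(x$unit_id),
    time = as.numeric(x$time)
  )
  out <- dplyr::arrange(out, .data$unit_id, .data$time)
  if (nrow(out) > 0 && (min(out$time) < 0 || max(out$time) > duration)) {
    abort_config("spike times must lie in [0, duration]")
  }
  attr(out, "duration") <- duration
  attr(out, "nominal_rate") <- nominal_rate
  attr(out, "nominal_correlation") <- nominal_correlation
  attr(out, "refractory_ms") <- refractory_ms
  attr(out, "seed") <- seed
  class(out) <- c("spike_trains", class(out))
  out
}

# Split a spike_trains tibble into a named list of per-unit sorted time
# vectors, including empty units listed in `unit_ids`.
train_list <- function(trains, unit_ids = NULL) {
  ids <- unit_ids %||% sort(unique(trains$unit_id))
  out <- lapply(ids, function(u) trains$time[trains$unit_id == u])
  names(out) <- as.character(ids)
  out
}

st_duration <- function(trains, duration = NULL) {
  d <- duration %||% attr(trains, "duration")
  if (is.null(d)) abort_config("`duration` missing: pass it or use a `spike_trains` object")
  d
}

#' Enforce a refractory period by greedy pruning
#'
#' Scans a sorted spike time vector in time order and deletes every spike
#' closer than `refractory_ms` to the last *kept* spike, so the output's
#' minimum inter-spike interval is at least the refractory period. The earlier
#' spike of a violating pair is always the one kept.
#'
#' @param times Sorted numeric vector of spike times (s).
#' @param refractory_ms Refractory period (ms).
#' @return Sorted, pruned time vector (a subset of the input).
#' @examples
#' prune_refractory(c(0, 0.003, 0.010), 4)
#' @export
prune_refractory <- function(times, refractory_ms) {
  check_non_negative(refractory_ms, "refractory_ms")
  if (length(times) < 2 || refractory_ms == 0) {
    return(times)
  }
  if (is.unsorted(times)) abort_config("`times` must be sorted")
  r <- refractory_ms / 1000
  # Vectorised rounds: each round removes the first spike of every violation
  # run; equivalent to the sequential keep-the-earlier scan.
  repeat {
    d <- diff(times)
    v <- which(d < r) + 1L
    if (length(v) == 0L) {
      return(times)
    }
    first_of_run <- v[c(TRUE, diff(v) > 1L)]
    times <- times[-first_of_run]
  }
}

# Poisson spike train on [0, duration] at `rate` Hz (uses the current RNG).
rpoisson_train <- function(rate, duration) {
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}

# Prune + iterative top-up so the empirical rate lands within `tol` of the
# nominal rate (uses current RNG). Refractory pruning alone undershoots the
# nominal rate by about rate * refractory; topping up with fresh independent
# Poisson spikes and re-pruning converges in a few rounds.
compensate_rate <- function(times, rate, duration, refractory_ms,
                            rounds = 5, tol = 0.01) {
  times <- prune_refractory(sort(times), refractory_ms)
  if (duration <= 0) {
    return(times)
  }
  for (k in seq_len(rounds)) {
    deficit <- rate - length(times) / duration
    if (deficit / rate <= tol) break
    extra <- rpoisson_train(deficit, duration)
    times <- prune_refractory(sort(c(times, extra)), refractory_ms)
  }
  times
}

check_rate_refractory <- function(rate, refractory_ms) {
  check_positive(rate, "rate")
  check_non_negative(refractory_ms, "refractory_ms")
  if (rate * refractory_ms / 1000 >= 1) {
    abort_config("infeasible configuration: rate * refractory >= 1")
  }
}

#' Generate independent Poisson spike trains
#'
#' Each unit fires as an independent homogeneous Poisson process at `rate`,
#' pruned to respect the refractory period and then topped up with additional
#' independent Poisson spikes (re-pruned, up to 5 rounds) so the empirical
#' rate stays close to the nominal one. Per-unit RNG streams are derived from
#' `seed`, so results are reproducible and unit-wise independent.
#'
#' @param n_units Number of units.
#' @param rate Firing rate (Hz).
#' @param duration Duration (s). A zero duration yields an empty train set
#'   with a warning.
#' @param refractory_ms Refractory period (ms); spikes violating it are
#'   pruned, keeping the earlier spike.
#' @param seed Integer master seed.
#' @return A `spike_trains` tibble (see [as_spike_trains()]).
#' @examples
#' st <- generate_independent(3, rate = 5, duration = 10, seed = 1)
#' nrow(st) / 3 / 10  # empirical rate, approx. 5 Hz
#' @export
generate_independent <- function(n_units, rate, duration, refractory_ms = 4, seed = 1) {
  check_positive(n_units, "n_units")
  check_rate_refractory(rate, refractory_ms)
  check_non_negative(duration, "duration")
  if (duration == 0) {
    warn("zero duration: returning an empty spike train set")
    return(as_spike_trains(
      tibble::tibble(unit_id = integer(), time = numeric()),
      duration = 0, nominal_rate = rate, nominal_correlation = 0,
      refractory_ms = refractory_ms, seed = as.integer(seed)
    ))
  }
  per_unit <- lapply(seq_len(n_units), function(u) {
    with_seed(derive_seed(seed, u), {
      compensate_rate(rpoisson_train(rate, duration), rate, duration, refractory_ms)
    })
  })
  df <- tibble::tibble(
    unit_id = rep(seq_len(n_units), lengths(per_unit)),
    time = flat_num(per_unit)
  )
  as_spike_trains(df, duration,
    nominal_rate = rate, nominal_correlation = 0,
    refractory_ms = refractory_ms, seed = as.integer(seed)
  )
}

#' Generate correlated spike trains via a mixture process
#'
#' Implements a mother-process construction of pairwise-correlated Poisson
#' trains with a Gaussian cross-correlogram profile: a shared mother Poisson
#' process runs at the nominal `rate`; each unit copies every mother spike
#' independently with probability `correlation`, jittering the copy by a
#' zero-mean Gaussian with sd `jitter_ms`, and adds an independent Poisson
#' component at `rate * (1 - correlation)`. The merged train is sorted,
#' refractory-pruned, and rate-compensated as in [generate_independent()].
#' Every pair of units then shares a fraction of about `correlation^2` of
#' coincident (jittered) spikes, which shows up as a Gaussian-shaped central
#' excess in the cross-correlogram.
#'
#' @inheritParams generate_independent
#' @param correlation Copy probability in `[0, 1)`; `0` reduces exactly to
#'   independent trains.
#' @param jitter_ms Gaussian jitter sd (ms) applied to copied mother spikes.
#' @return A `spike_trains` tibble.
#' @export
generate_correlated <- function(n_units, rate, correlation, jitter_ms = 0.5,
                                duration = 300, refractory_ms = 4, seed = 1) {
  check_positive(n_units, "n_units")
  check_rate_refractory(rate, refractory_ms)
  check_non_negative(duration, "duration")
  if (!is.numeric(correlation) || length(correlation) != 1L ||
      correlation < 0 || correlation >= 1) {
    abort_config("`correlation` must lie in [0, 1)")
  }
  if (correlation > 0) check_positive(jitter_ms, "jitter_ms")
  if (duration == 0) {
    warn("zero duration: returning an empty spike train set")
    return(as_spike_trains(
      tibble::tibble(unit_id = integer(), time = numeric()),
      duration = 0, nominal_rate = rate, nominal_correlation = correlation,
      refractory_ms = refractory_ms, seed = as.integer(seed)
    ))
  }

  mother <- if (correlation > 0) {
    with_seed(derive_seed(seed, 0L), rpoisson_train(rate, duration))
  } else {
    numeric(0)
  }

  per_unit <- lapply(seq_len(n_units), function(u) {
    with_seed(derive_seed(seed, u), {
      if (correlation > 0) {
        keep <- runif(length(mother)) < correlation
        copied <- mother[keep] + rnorm(sum(keep), 0, jitter_ms / 1000)
        copied <- copied[copied >= 0 & copied <= duration]
        indep <- rpoisson_train(rate * (1 - correlation), duration)
        merged <- sort(c(copied, indep))
      } else {
        merged <- rpoisson_train(rate, duration)
      }
      compensate_rate(merged, rate, duration, refractory_ms)
    })
  })
  df <- tibble::tibble(
    unit_id = rep(seq_len(n_units), lengths(per_unit)),
    time = flat_num(per_unit)
  )
  as_spike_trains(df, duration,
    nominal_rate = rate, nominal_correlation = correlation,
    refractory_ms = refractory_ms, seed = as.integer(seed)
  )
}

#' Write / read spike trains as TSV plus JSON sidecar
#'
#' The table `<path>` holds two tab-separated columns, `unit_id` and `time_s`;
#' the sidecar `<path>.json` records duration and generation metadata.
#'
#' @param trains A `spike_trains` tibble.
#' @param path File path (sidecar is `<path>.json`).
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` a `spike_trains` tibble.
#' @export
write_spike_trains <- function(trains, path) {
  df <- data.frame(unit_id = trains$unit_id, time_s = format(trains$time, digits = 17))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    duration = attr(trains, "duration"),
    nominal_rate = attr(trains, "nominal_rate"),
    nominal_correlation = attr(trains, "nominal_correlation"),
    refractory_ms = attr(trains, "refractory_ms"),
    seed = attr(trains, "seed")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  as_spike_trains(
    tibble::tibble(unit_id = df$unit_id, time = df$time_s),
    duration = meta$duration,
    nominal_rate = meta$nominal_rate %||% NA_real_,
    nominal_correlation = meta$nominal_correlation %||% NA_real_,
    refractory_ms = meta$refractory_ms %||% NA_real_,
    seed = meta$seed %||% NA_integer_
  )
}
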
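#' Benchmark configuration
#'
#' Bundles every parameter of the simulation-and-evaluation grid: firing
#' rates x correlation levels, replicate count, recording parameters and the
#' metric settings. The default profile is desk-scale (300 s, 2 replicates);
#' `paper_scale = TRUE` switches to the full-scale profile (30-minute
#' recordings, 5 replicates per condition, hence 3 x 3 x 5 = 45 runs).
#'
#' Within a condition, replicates share the spike trains but redraw the
#' templates and unit positions: the spike-train seed depends only on the
#' condition while the template seed varies per replicate. This populates the
#' template-similarity axis across replicates without confounding it with
#' spike timing.
#'
#' @param rates Firing rate levels (Hz).
#' @param correlations Correlation levels in `[0, 1)`.
#' @param n_seeds Replicates per condition.
#' @param duration Recording duration (s).
#' @param n_units Units per recording.
#' @param noise_sd Noise SD (uV).
#' @param amp_mod_sd Amplitude modulation SD (fraction).
#' @param sampling_rate Sampling rate (Hz).
#' @param jitter_ms Mixture-process jitter SD (ms).
#' @param refractory_ms Refractory period (ms).
#' @param probe A `probe_layout`.
#' @param master_seed Master seed; all per-run seeds derive from it.
#' @param delta_ms Spike matching window (ms).
#' @param collision_window_ms Synchrony window (ms).
#' @param n_lag_bins Number of collision lag bins.
#' @param similarity_bins Similarity bin edges for pooling.
#' @param ccg_bin_ms,ccg_window_ms,ccg_sim_threshold Correlogram-error
#'   settings.
#' @param out_dir Optional output directory for per-run files.
#' @param paper_scale If `TRUE`, use the full-scale profile defaults.
#' @return A `bench_config` object.
#' @export
bench_config <- function(rates = c(5, 10, 15),
                         correlations = c(0, 0.1, 0.2),
                         n_seeds = if (paper_scale) 5 else 2,
                         duration = if (paper_scale) 1800 else 300,
                         n_units = 20,
                         noise_sd = 5,
                         amp_mod_sd = 0.05,
                         sampling_rate = 32000,
                         jitter_ms = 0.5,
                         refractory_ms = 4,
                         probe = make_probe(),
                         master_seed = 42,
                         delta_ms = 0.4,
                         collision_window_ms = 2,
                         n_lag_bins = 11,
                         similarity_bins = seq(-0.4, 1, by = 0.2),
                         ccg_bin_ms = 0.5,
                         ccg_window_ms = 10,
                         ccg_sim_threshold = 0.5,
                         out_dir = NULL,
                         paper_scale = FALSE) {
  if (any(rates <= 0)) abort_config("all rates must be positive")
  if (any(correlations < 0 | correlations >= 1)) {
    abort_config("correlations must lie in [0, 1)")
  }
  if (n_seeds < 1) abort_config("`n_seeds` must be at least 1")
  check_positive(duration, "duration")
  cfg <- list(
    rates = rates, correlations = correlations, n_seeds = as.integer(n_seeds),
    duration = duration, n_units = as.integer(n_units), noise_sd = noise_sd,
    amp_mod_sd = amp_mod_sd, sampling_rate = sampling_rate,
    jitter_ms = jitter_ms, refractory_ms = refractory_ms, probe = probe,
    master_seed = as.integer(master_seed), delta_ms = delta_ms,
    collision_window_ms = collision_window_ms,
    n_lag_bins = as.integer(n_lag_bins), similarity_bins = similarity_bins,
    ccg_bin_ms = ccg_bin_ms, ccg_window_ms = ccg_window_ms,
    ccg_sim_threshold = ccg_sim_threshold, out_dir = out_dir
  )
  structure(cfg, class = "bench_config")
}

#' @export
print.bench_config <- function(x, ...) {
  cat(sprintf(
    "<bench_config> %d rates x %d correlations x %d seeds = %d runs; %.0f s, %d units\n",
    length(x$rates), length(x$correlations), x$n_seeds,
    length(x$rates) * length(x$correlations) * x$n_seeds,
    x$duration, x$n_units
  ))
  invisible(x)
}

# Enumerate the run table with all derived seeds.
enumerate_runs <- function(config) {
  grid <- tidyr::crossing(
    rate = config$rates,
    correlation = config$correlations
  )
  grid$cond_idx <- seq_len(nrow(grid))
  runs <- tidyr::crossing(grid, replicate = seq_len(config$n_seeds))
  runs |>
    dplyr::mutate(
      run_id = sprintf("r%g_c%g_s%d", .data$rate, 100 * .data$correlation,
                       .data$replicate),
      train_seed = derive_seed(config$master_seed, 10L * .data$cond_idx),
      template_seed = derive_seed(config$master_seed,
                                  1000L + 100L * .data$cond_idx + .data$replicate),
      recording_seed = derive_seed(config$master_seed,
                                   5000L + 100L * .data$cond_idx + .data$replicate),
      sorter_seed = derive_seed(config$master_seed,
                                9000L + 100L * .data$cond_idx + .data$replicate)
    ) |>
    dplyr::select("run_id", "cond_idx", "rate", "correlation", "replicate",
                  dplyr::ends_with("_seed"))
}

run_one <- function(config, run, sorter, sorter_args) {
  trains <- if (run$correlation > 0) {
    generate_correlated(config$n_units, run$rate, run$correlation,
                        config$jitter_ms, config$duration,
                        config$refractory_ms, run$train_seed)
  } else {
    generate_independent(config$n_units, run$rate, config$duration,
                         config$refractory_ms, run$train_seed)
  }
  templates <- synthesize_templates(
    config$probe, config$n_units,
    sampling_rate = config$sampling_rate, seed = run$template_seed
  )
  sim <- cosine_similarity(templates)
  events <- find_synchronous_events(trains, config$collision_window_ms)

  sorted <- switch(sorter,
    oracle = oracle_sorter(trains),
    degraded = {
      model <- sorter_args$model %||%
        degradation_model(p_drop = 0.3, seed = run$sorter_seed)
      degraded_oracle(trains, events, model, sim)
    },
    greedy = {
      rec <- assemble_recording(templates, trains, config$noise_sd,
                                config$amp_mod_sd, run$recording_seed)
      do.call(greedy_tm_sorter, c(list(rec, templates), sorter_args))
    },
    abort_config(sprintf("unknown built-in sorter '%s'", sorter))
  )

  cmp <- compare_sortings(trains, sorted, config$delta_ms)
  profiles <- collision_recall_by_lag(events, cmp, config$n_lag_bins,
                                      config$collision_window_ms)
  profiles$similarity <- pair_similarity(sim, profiles$unit_i, profiles$unit_j)
  pooled <- pool_profiles_by_similarity(profiles, sim, config$similarity_bins)
  by_sim <- collision_recall_by_similarity(pooled)
  ccg_err <- tryCatch(
    correlogram_relative_error(trains, sorted, cmp, sim,
                               config$ccg_sim_threshold,
                               config$ccg_bin_ms, config$ccg_window_ms),
    error = function(e) NULL
  )
  list(
    summary = glance(cmp),
    profiles = profiles,
    pooled = pooled,
    by_similarity = by_sim,
    ccg_error = ccg_err
  )
}

write_run_outputs <- function(config, run, res, trains = NULL, sorted = NULL) {
  dir <- file.path(config$out_dir, run$run_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snap <- c(
    run,
    list(duration = config$duration, n_units = config$n_units,
         noise_sd = config$noise_sd, master_seed = config$master_seed)
  )
  jsonlite::write_json(snap, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(res$pooled, file.path(dir, "collision_by_lag.csv"),
                   row.names = FALSE)
  utils::write.csv(res$by_similarity, file.path(dir, "collision_by_similarity.csv"),
                   row.names = FALSE)
  if (!is.null(res$ccg_error)) {
    utils::write.csv(res$ccg_error, file.path(dir, "ccg_error.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Run the benchmark grid
#'
#' Executes one simulated recording and its full evaluation per
#' (rate, correlation, replicate) cell of the configured grid, with the
#' selected built-in sorter, and collects per-run results. Failures in
#' individual runs are caught and reported in the `status` column; the grid
#' continues. With `dry_run = TRUE` only the run table (including all derived
#' seeds) is returned — useful for bookkeeping checks.
#'
#' @param config A [bench_config()].
#' @param sorter One of `"oracle"`, `"degraded"`, `"greedy"`.
#' @param sorter_args List of extra arguments for the sorter (for
#'   `"degraded"`, a `model`; for `"greedy"`, arguments of
#'   [greedy_tm_sorter()]).
#' @param dry_run If `TRUE`, enumerate the runs without executing them.
#' @return A `bench_results` tibble: one row per run with identification
#'   columns, `status`, and list-columns `summary`, `profiles`, `pooled`,
#'   `by_similarity`, `ccg_error`.
#' @export
run_grid <- function(config, sorter = c("oracle", "degraded", "greedy"),
                     sorter_args = list(), dry_run = FALSE) {
  stopifnot(inherits(config, "bench_config"))
  sorter <- match.arg(sorter)
  runs <- enumerate_runs(config)
  if (dry_run) {
    return(runs)
  }
  results <- purrr::pmap(runs, function(...) {
    run <- list(...)
    tryCatch(
      {
        res <- run_one(config, run, sorter, sorter_args)
        if (!is.null(config$out_dir)) write_run_outputs(config, run, res)
        c(res, list(status = "ok", message = NA_character_))
      },
      error = function(e) {
        warn(sprintf("run %s failed: %s", run$run_id, conditionMessage(e)))
        list(summary = NULL, profiles = NULL, pooled = NULL,
             by_similarity = NULL, ccg_error = NULL,
             status = "error", message = conditionMessage(e))
      }
    )
  })
  out <- runs
  out$status <- purrr::map_chr(results, "status")
  out$message <- purrr::map_chr(results, "message")
  out$summary <- purrr::map(results, "summary")
  out$profiles <- purrr::map(results, "profiles")
  out$pooled <- purrr::map(results, "pooled")
  out$by_similarity <- purrr::map(results, "by_similarity")
  out$ccg_error <- purrr::map(results, "ccg_error")
  attr(out, "config") <- config
  attr(out, "sorter") <- sorter
  class(out) <- c("bench_results", class(out))
  out
}

#' Aggregate benchmark results across conditions
#'
#' Averages the per-run outputs over all successful runs: the collision
#' recall per lag bin (restricted to pairs with template similarity above
#' `sim_min`, event-weighted within run), the collision recall per similarity
#' bin, the global unit metrics, and the correlogram relative error per lag.
#' The spread across runs is reported as the sample standard deviation
#' (denominator n - 1). Runs must share identical bin configurations.
#'
#' @param results A `bench_results` from [run_grid()].
#' @param sim_min Only pairs with similarity above this enter the lag curve.
#' @return A `bench_report`: list of tibbles `collision_by_lag`,
#'   `collision_by_similarity`, `metrics`, `ccg_error`.
#' @export
aggregate_report <- function(results, sim_min = 0.5) {
  stopifnot(inherits(results, "bench_results"))
  ok <- results[results$status == "ok", ]
  if (nrow(ok) == 0) abort_config("no successful runs to aggregate")

  edge_list <- lapply(ok$profiles, attr, "bin_edges_ms")
  if (length(unique(lapply(edge_list, as.numeric))) != 1) {
    abort_config("runs have mixed lag-bin configurations")
  }

  lag_curves <- purrr::imap_dfr(ok$profiles, function(p, i) {
    p |>
      dplyr::filter(.data$similarity > sim_min) |>
      dplyr::group_by(.data$bin, .data$lag_ms) |>
      dplyr::summarise(
        recall = if (sum(.data$n_spikes) > 0) {
          sum(.data$n_tp) / sum(.data$n_spikes)
        } else {
          NA_real_
        },
        .groups = "drop"
      ) |>
      dplyr::mutate(run = i)
  })
  collision_by_lag <- lag_curves |>
    dplyr::group_by(.data$bin, .data$lag_ms) |>
    dplyr::summarise(
      mean_recall = mean(.data$recall, na.rm = TRUE),
      sd_recall = sd(.data$recall, na.rm = TRUE),
      n_runs = sum(!is.na(.data$recall)),
      .groups = "drop"
    )

  sim_curves <- purrr::imap_dfr(ok$by_similarity, ~ dplyr::mutate(.x, run = .y))
  collision_by_similarity <- sim_curves |>
    dplyr::group_by(.data$sim_lo, .data$sim_hi) |>
    dplyr::summarise(
      mean_recall = mean(.data$recall, na.rm = TRUE),
      sd_recall = sd(.data$recall, na.rm = TRUE),
      n_runs = sum(!is.na(.data$recall)),
      .groups = "drop"
    )

  metrics <- purrr::imap_dfr(ok$summary, ~ dplyr::mutate(.x, run = .y)) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "precision", "recall"),
      list(mean = mean, sd = sd)
    ))

  ccg_list <- purrr::compact(ok$ccg_error)
  ccg_error <- NULL
  if (length(ccg_list) > 0) {
    ccg_error <- purrr::imap_dfr(ccg_list, ~ dplyr::mutate(.x, run = .y)) |>
      dplyr::group_by(.data$lag_ms) |>
      dplyr::summarise(
        mean_error = mean(.data$mean_relative_error),
        sd_error = sd(.data$mean_relative_error),
        n_runs = dplyr::n(),
        .groups = "drop"
      )
  }

  structure(
    list(
      collision_by_lag = collision_by_lag,
      collision_by_similarity = collision_by_similarity,
      metrics = metrics,
      ccg_error = ccg_error,
      n_runs = nrow(ok)
    ),
    class = "bench_report"
  )
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf("<bench_report> aggregated over %d runs\n", x$n_runs))
  cat(sprintf(
    "  mean accuracy %.3f, precision %.3f, recall %.3f\n",
    x$metrics$accuracy_mean, x$metrics$precision_mean, x$metrics$recall_mean
  ))
  invisible(x)
}
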
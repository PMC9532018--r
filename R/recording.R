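#' Assemble an extracellular recording from templates and spike trains
#'
#' For every ground-truth spike the unit's template, scaled by an i.i.d.
#' multiplicative amplitude factor (Gaussian, mean 1, sd `amp_mod_sd`,
#' truncated to `[0.7, 1.3]`), is added to the traces with its peak at the
#' nearest sample; i.i.d. Gaussian noise of sd `noise_sd` uV is added to every
#' sample of every channel. Templates overlapping the recording ends are
#' truncated.
#'
#' Traces are generated (and written) in chunks of `chunk_s` seconds so that
#' long recordings never have to be held in memory: the returned object stores
#' the generation parameters and draws any requested sample range on demand,
#' deterministically under `seed` (noise is seeded per chunk, amplitude
#' factors per spike). Use [get_traces()] to materialize a range.
#'
#' @param templates A `template_set`.
#' @param trains A `spike_trains` tibble; unit ids must exist in `templates`.
#' @param noise_sd Noise standard deviation (uV).
#' @param amp_mod_sd Sd of the multiplicative amplitude modulation (fraction).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   traces.
#' @param duration Duration (s); defaults to the trains' duration.
#' @param chunk_s Chunk length (s) for generation and file I/O.
#' @return A `recording` object: `sampling_rate`, `duration`, `n_samples`,
#'   `n_channels`, `probe`, plus the generation parameters.
#' @examples
#' probe <- make_probe(8, 2, 18, 22)
#' ts <- synthesize_templates(probe, n_units = 2, seed = 1, similarity_span = c(1, -1))
#' st <- generate_independent(2, 5, 2, seed = 1)
#' rec <- assemble_recording(ts, st, noise_sd = 5, seed = 1)
#' dim(get_traces(rec, 1, 100))
#' @export
assemble_recording <- function(templates, trains, noise_sd = 5, amp_mod_sd = 0.05,
                               seed = 1, duration = NULL, chunk_s = 10) {
  stopifnot(inherits(templates, "template_set"))
  check_non_negative(noise_sd, "noise_sd")
  check_non_negative(amp_mod_sd, "amp_mod_sd")
  check_positive(chunk_s, "chunk_s")
  duration <- st_duration(trains, duration)
  check_positive(duration, "duration")
  d <- dim(templates$waveforms)
  n_units <- d[1]
  if (nrow(trains) > 0 && (min(trains$unit_id) < 1 || max(trains$unit_id) > n_units)) {
    abort("spike train unit ids do not match the template set")
  }
  fs <- templates$sampling_rate
  n_samples <- as.integer(round(duration * fs))

  # spikes are inserted with the template's negative peak at the spike sample
  peak_idx <- template_peak_index(templates)

  amps <- with_seed(derive_seed(seed, 1L), {
    a <- rnorm(nrow(trains), 1, amp_mod_sd)
    while (any(bad <- a < 0.7 | a > 1.3)) {
      a[bad] <- rnorm(sum(bad), 1, amp_mod_sd)
    }
    a
  })

  spikes <- tibble::tibble(
    unit_id = trains$unit_id,
    time = trains$time,
    sample = as.integer(round(trains$time * fs)) + 1L,
    amp = if (nrow(trains) > 0) amps else numeric(0)
  )

  structure(
    list(
      kind = "synth",
      sampling_rate = fs,
      duration = duration,
      n_samples = n_samples,
      n_channels = d[3],
      probe = templates$probe,
      templates = templates,
      spikes = spikes,
      peak_idx = peak_idx,
      noise_sd = noise_sd,
      amp_mod_sd = amp_mod_sd,
      seed = as.integer(seed),
      chunk_samples = as.integer(round(chunk_s * fs)),
      traces = NULL
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %.1f s at %g kHz, %d channels (%s)\n",
    x$duration, x$sampling_rate / 1000, x$n_channels,
    if (is.null(x$traces)) "lazy, chunked" else "in memory"
  ))
  invisible(x)
}

#' Materialize a sample range of a recording
#'
#' @param rec A `recording`.
#' @param first,last 1-based first and last sample (defaults: whole
#'   recording).
#' @return A numeric matrix `samples x channels` in uV.
#' @export
get_traces <- function(rec, first = 1L, last = rec$n_samples) {
  stopifnot(inherits(rec, "recording"))
  first <- max(1L, as.integer(first))
  last <- min(rec$n_samples, as.integer(last))
  if (last < first) abort_config("empty sample range")
  if (!is.null(rec$traces)) {
    return(rec$traces[first:last, , drop = FALSE])
  }
  n <- last - first + 1L
  out <- matrix(0, n, rec$n_channels)
  cs <- rec$chunk_samples
  k0 <- (first - 1L) %/% cs
  k1 <- (last - 1L) %/% cs
  if (rec$noise_sd > 0) {
    for (k in k0:k1) {
      a <- k * cs + 1L
      b <- min((k + 1L) * cs, rec$n_samples)
      chunk_noise <- with_seed(derive_seed(rec$seed, 100000L + k), {
        x <- rnorm((b - a + 1L) * rec$n_channels, 0, rec$noise_sd)
        dim(x) <- c(b - a + 1L, rec$n_channels)
        x
      })
      lo <- max(a, first)
      hi <- min(b, last)
      out[(lo - first + 1L):(hi - first + 1L), ] <-
        chunk_noise[(lo - a + 1L):(hi - a + 1L), , drop = FALSE]
    }
  }
  add_spikes_range(out, rec, first, last)
}

# Add all template insertions whose support intersects [first, last] to `mat`
# (a (last-first+1) x C matrix aligned at `first`).
add_spikes_range <- function(mat, rec, first, last) {
  sp <- rec$spikes
  if (nrow(sp) == 0) {
    return(mat)
  }
  tlen <- dim(rec$templates$waveforms)[2]
  starts <- sp$sample - rec$peak_idx[sp$unit_id] + 1L
  keep <- which(starts <= last & (starts + tlen - 1L) >= first)
  for (s in keep) {
    st <- starts[s]
    w_rows <- max(first, st):min(last, st + tlen - 1L)
    t_rows <- w_rows - st + 1L
    mat[w_rows - first + 1L, ] <- mat[w_rows - first + 1L, ] +
      sp$amp[s] * rec$templates$waveforms[sp$unit_id[s], t_rows, ]
  }
  mat
}

#' Robust per-channel noise estimate
#'
#' Median absolute deviation of each channel, scaled to the standard
#' deviation of a Gaussian (constant 1.4826). The estimate is computed on up
#' to `max_s` seconds of data, so it is robust to the sparse spike content of
#' typical recordings.
#'
#' @param rec A `recording`.
#' @param max_s Maximum amount of data used (s).
#' @return Numeric vector of per-channel noise SDs (uV).
#' @export
estimate_noise <- function(rec, max_s = 10) {
  stopifnot(inherits(rec, "recording"))
  n <- min(rec$n_samples, as.integer(round(max_s * rec$sampling_rate)))
  tr <- get_traces(rec, 1L, n)
  apply(tr, 2, stats::mad)
}

#' Write / read raw binary recordings
#'
#' Traces are streamed chunk-wise to `<path>` as flat little-endian float32,
#' channel-interleaved (all channels of sample 1, then sample 2, ...), with a
#' JSON sidecar `<path>.json` holding `sampling_rate`, `n_channels`, `dtype`,
#' `order`, `units` ("uV"), duration and seed. Write-read-write round trips
#' are bit-exact.
#'
#' @param rec A `recording`.
#' @param path Binary file path (sidecar is `<path>.json`).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   an in-memory `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  cs <- rec$chunk_samples
  k <- 0L
  while (k * cs < rec$n_samples) {
    a <- k * cs + 1L
    b <- min((k + 1L) * cs, rec$n_samples)
    chunk <- get_traces(rec, a, b)
    writeBin(as.vector(t(chunk)), con, size = 4, endian = "little")
    k <- k + 1L
  }
  meta <- list(
    dtype = "float32", order = "interleaved", units = "uV",
    sampling_rate = rec$sampling_rate,
    n_channels = rec$n_channels,
    n_samples = rec$n_samples,
    duration = rec$duration,
    seed = rec$seed,
    probe = list(
      channel_ids = rec$probe$channel_id, x = rec$probe$x, y = rec$probe$y,
      pitch_x = attr(rec$probe, "pitch_x"), pitch_y = attr(rec$probe, "pitch_y"),
      n_columns = attr(rec$probe, "n_columns")
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_samples <- as.integer(meta$n_samples)
  n_channels <- as.integer(meta$n_channels)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = n_samples * n_channels, size = 4,
                  endian = "little")
  traces <- matrix(vals, nrow = n_samples, ncol = n_channels, byrow = TRUE)
  probe <- NULL
  if (!is.null(meta$probe)) {
    probe <- tibble::tibble(
      channel_id = as.integer(meta$probe$channel_ids),
      x = as.numeric(meta$probe$x), y = as.numeric(meta$probe$y)
    )
    attr(probe, "pitch_x") <- meta$probe$pitch_x
    attr(probe, "pitch_y") <- meta$probe$pitch_y
    attr(probe, "n_columns") <- meta$probe$n_columns
    class(probe) <- c("probe_layout", class(probe))
  }
  structure(
    list(
      kind = "memory",
      sampling_rate = meta$sampling_rate,
      duration = meta$duration,
      n_samples = n_samples,
      n_channels = n_channels,
      probe = probe,
      templates = NULL,
      spikes = tibble::tibble(unit_id = integer(), time = numeric(),
                              sample = integer(), amp = numeric()),
      peak_idx = integer(),
      noise_sd = NA_real_,
      amp_mod_sd = NA_real_,
      seed = as.integer(meta$seed %||% NA_integer_),
      chunk_samples = as.integer(round(10 * meta$sampling_rate)),
      traces = traces
    ),
    class = "recording"
  )
}
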
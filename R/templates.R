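#' Synthesize parametric extracellular templates for a probe
#'
#' Builds a set of per-unit spatiotemporal templates from a compact parametric
#' model rather than a biophysical simulation. Each unit is a point source
#' placed at a random position near the probe plane (with a perpendicular
#' offset `z`). Its waveform on every channel is
#'
#' \deqn{W(t, c) = a_{main}(c)\, k(t) - a_{ret}(c)\, k(t - \delta)}
#'
#' where `k(t)` is a difference of two Gaussians (a sharp negative spike lobe
#' followed by a slower positive after-wave, normalized to a unit negative
#' peak) and the amplitudes decay with distance `d` from the source as
#' `a(d) = A / (1 + (d/lambda)^2)`. The second, polarity-inverted term models
#' the dendritic return current: a weaker source displaced along a random
#' in-plane axis. Channels that sit closer to the return source than to the
#' soma see a predominantly positive deflection, which is what makes strongly
#' negative pairwise cosine similarities achievable.
#'
#' Unit placement is rejected and redrawn (up to `max_attempts` per unit) if
#' the resulting peak-channel amplitude falls below `min_peak_uv`, so every
#' accepted unit is detectable. The whole placement is resampled (up to
#' `max_resample` times, deterministically under `seed`) until the pairwise
#' cosine similarities span at least `similarity_span`, so that downstream
#' collision analyses can populate the similarity axis; if no draw achieves
#' the span the widest-spanning draw is kept with a warning.
#'
#' @param probe A `probe_layout` from [make_probe()].
#' @param n_units Number of units.
#' @param amplitude_range Range (uV) of the peak amplitude drawn per unit,
#'   defined at the unit's perpendicular distance from the probe plane.
#' @param duration_ms Template duration (ms).
#' @param sampling_rate Sampling rate (Hz).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param decay_lambda Spatial decay constant lambda (um).
#' @param z_range Range of the perpendicular source-to-plane distance (um).
#' @param min_peak_uv Minimum acceptable peak-channel amplitude (uV).
#' @param margin_um In-plane placement margin around the probe bounding box (um).
#' @param return_frac_range Range of the return-current amplitude as a
#'   fraction of the soma amplitude.
#' @param return_dist_range Range of the soma-to-return-source displacement (um).
#' @param similarity_span Required span `c(lo, hi)` of off-diagonal cosine
#'   similarities.
#' @param max_attempts Per-unit redraw budget for the amplitude constraint.
#' @param max_resample Whole-set redraw budget for the similarity span.
#'
#' @return A `template_set`: list with `waveforms` (array
#'   `n_units x n_samples x n_channels`, uV), `sampling_rate`, `unit_positions`
#'   (tibble `unit_id, x, y, z`), and `probe`.
#' @examples
#' probe <- make_probe()
#' ts <- synthesize_templates(probe, n_units = 8, seed = 1)
#' dim(ts$waveforms)
#' @export
synthesize_templates <- function(probe,
                                 n_units = 20,
                                 amplitude_range = c(30, 200),
                                 duration_ms = 5,
                                 sampling_rate = 32000,
                                 seed = 1,
                                 decay_lambda = 30,
                                 z_range = c(10, 60),
                                 min_peak_uv = 30,
                                 margin_um = 25,
                                 return_frac_range = c(0.4, 0.8),
                                 return_dist_range = c(40, 90),
                                 similarity_span = c(-0.2, 0.8),
                                 max_attempts = 100,
                                 max_resample = 50) {
  stopifnot(inherits(probe, "probe_layout"))
  check_positive(n_units, "n_units")
  check_positive(duration_ms, "duration_ms")
  check_positive(sampling_rate, "sampling_rate")
  if (amplitude_range[1] > amplitude_range[2]) {
    abort_config("`amplitude_range` must be increasing.")
  }
  n_units <- as.integer(n_units)
  n_samples <- max(2L, as.integer(round(duration_ms / 1000 * sampling_rate)))
  n_channels <- nrow(probe)

  # temporal kernels (ms grid), frozen shape parameters
  t_ms <- (seq_len(n_samples) - 1) / sampling_rate * 1000
  t0 <- min(1.5, duration_ms * 0.3)
  kern <- function(tt) {
    -exp(-(tt - t0)^2 / (2 * 0.2^2)) + 0.35 * exp(-(tt - t0 - 0.7)^2 / (2 * 0.6^2))
  }
  k_main <- kern(t_ms)
  k_main <- k_main / abs(min(k_main))     # unit negative peak
  k_ret <- -kern(t_ms - 0.15)             # polarity-inverted, slightly delayed
  k_ret <- k_ret / abs(max(k_ret))

  xr <- range(probe$x) + c(-margin_um, margin_um)
  yr <- range(probe$y) + c(-margin_um, margin_um)
  lam2 <- decay_lambda^2

  draw_set <- function(sub_seed) {
    with_seed(sub_seed, {
      waves <- array(0, dim = c(n_units, n_samples, n_channels))
      pos <- matrix(NA_real_, n_units, 3)
      for (u in seq_len(n_units)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          px <- runif(1, xr[1], xr[2])
          py <- runif(1, yr[1], yr[2])
          pz <- runif(1, z_range[1], z_range[2])
          a_peak <- runif(1, amplitude_range[1], amplitude_range[2])
          beta <- runif(1, return_frac_range[1], return_frac_range[2])
          phi <- runif(1, 0, 2 * pi)
          ret_l <- runif(1, return_dist_range[1], return_dist_range[2])
          rx <- px + ret_l * cos(phi)
          ry <- py + ret_l * sin(phi)

          a0 <- a_peak * (1 + pz^2 / lam2)
          d2_main <- (probe$x - px)^2 + (probe$y - py)^2 + pz^2
          d2_ret <- (probe$x - rx)^2 + (probe$y - ry)^2 + pz^2
          a_main <- a0 / (1 + d2_main / lam2)
          a_ret <- beta * a0 / (1 + d2_ret / lam2)

          w <- outer(k_main, a_main) + outer(k_ret, a_ret)  # samples x channels
          if (max(abs(w)) >= min_peak_uv) {
            waves[u, , ] <- w
            pos[u, ] <- c(px, py, pz)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "unit %d: could not satisfy the %.0f uV peak amplitude constraint in %d attempts",
            u, min_peak_uv, max_attempts
          ))
        }
      }
      list(waves = waves, pos = pos)
    })
  }

  finish <- function(drawn) {
    ts <- structure(
      list(
        waveforms = drawn$waves,
        sampling_rate = sampling_rate,
        unit_positions = tibble::tibble(
          unit_id = seq_len(n_units),
          x = drawn$pos[, 1], y = drawn$pos[, 2], z = drawn$pos[, 3]
        ),
        probe = probe
      ),
      class = "template_set"
    )
    ts
  }

  best <- NULL
  best_cover <- -Inf
  for (r in seq_len(max_resample)) {
    drawn <- draw_set(derive_seed(seed, r))
    ts <- finish(drawn)
    if (n_units < 2) {
      return(ts)
    }
    sim <- cosine_similarity(ts)
    off <- sim[upper.tri(sim)]
    cover <- min(0, similarity_span[1] - min(off)) + min(0, max(off) - similarity_span[2])
    if (min(off) <= similarity_span[1] && max(off) >= similarity_span[2]) {
      return(ts)
    }
    if (cover > best_cover) {
      best <- ts
      best_cover <- cover
    }
  }
  warn(sprintf(
    "pairwise similarities did not span [%.2f, %.2f] in %d placement draws; keeping the widest draw",
    similarity_span[1], similarity_span[2], max_resample
  ))
  best
}

#' @export
print.template_set <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf(
    "<template_set> %d units, %d samples (%.2f ms at %g kHz), %d channels\n",
    d[1], d[2], d[2] / x$sampling_rate * 1000, x$sampling_rate / 1000, d[3]
  ))
  pk <- apply(abs(x$waveforms), 1, max)
  cat(sprintf("  peak |amplitude|: %.1f - %.1f uV\n", min(pk), max(pk)))
  invisible(x)
}

# Flatten one unit's template by concatenating channels: vector of length T*C.
flatten_template <- function(waveforms, unit) {
  as.vector(waveforms[unit, , ])
}

# Per-unit peak sample: the sample of the most negative deflection across
# channels. Spike times refer to this sample, both when templates are
# inserted into traces and when the template-matching sorter reports times.
template_peak_index <- function(templates) {
  apply(apply(templates$waveforms, c(1, 2), min), 1, which.min)
}

#' Pairwise cosine similarity between templates
#'
#' Each unit's `T x C` template is flattened by concatenating channels and the
#' similarity of units i and j is the cosine of the angle between the two
#' flattened vectors: `dot(ti, tj) / (||ti|| ||tj||)`. Values lie in
#' `[-1, 1]`: 1 for parallel templates, -1 for anti-parallel ones and 0 for
#' orthogonal (non-overlapping) ones.
#'
#' @param templates A `template_set`.
#' @return A symmetric `n_units x n_units` matrix of class
#'   `similarity_matrix` with unit ids as dimnames and unit diagonal.
#' @export
cosine_similarity <- function(templates) {
  stopifnot(inherits(templates, "template_set"))
  d <- dim(templates$waveforms)
  n <- d[1]
  if (n < 1) abort_config("need at least one unit")
  flat <- matrix(templates$waveforms, nrow = n)  # n x (T*C), unit index fastest in array
  norms <- sqrt(rowSums(flat^2))
  if (any(norms == 0)) {
    abort(
      sprintf(
        "zero-norm template for unit(s): %s",
        paste(which(norms == 0), collapse = ", ")
      ),
      class = "spikecollide_zero_norm_error"
    )
  }
  sim <- tcrossprod(flat / norms)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  ids <- as.character(seq_len(n))
  dimnames(sim) <- list(ids, ids)
  class(sim) <- c("similarity_matrix", class(sim))
  sim
}

#' @exportS3Method
tidy.similarity_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    unit_i = as.integer(idx[, 1]),
    unit_j = as.integer(idx[, 2]),
    similarity = x[idx]
  )
}

#' Template barycenters
#'
#' Estimates each unit's position on the probe plane as the average of the
#' channel positions weighted by the per-channel peak absolute amplitude of
#' the unit's template (weights normalized to sum to one).
#'
#' @param templates A `template_set`.
#' @param probe A `probe_layout`; defaults to the one stored in `templates`.
#' @return A tibble with `unit_id`, `x`, `y` (um).
#' @export
template_barycenter <- function(templates, probe = templates$probe) {
  stopifnot(inherits(templates, "template_set"))
  d <- dim(templates$waveforms)
  if (nrow(probe) != d[3]) {
    abort_config("probe channel count does not match template channel count")
  }
  peak <- apply(abs(templates$waveforms), c(1, 3), max)  # units x channels
  w <- peak / rowSums(peak)
  tibble::tibble(
    unit_id = seq_len(d[1]),
    x = as.vector(w %*% probe$x),
    y = as.vector(w %*% probe$y)
  )
}

#' Persist a template set as flat float32 binary plus JSON sidecar
#'
#' `write_templates()` writes `<path>` (flat little-endian float32, array laid
#' out column-major over `unit x sample x channel`) and `<path>.json` with the
#' array dimensions, sampling rate, unit positions and units ("uV").
#' `read_templates()` reverses it. Round trips are bit-exact at float32
#' precision.
#'
#' @param templates A `template_set`.
#' @param path Binary file path (sidecar is `<path>.json`).
#' @return `write_templates()` returns `path` invisibly; `read_templates()`
#'   a `template_set`.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  d <- dim(templates$waveforms)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(templates$waveforms), con, size = 4, endian = "little")
  meta <- list(
    dims = d,
    dim_order = c("unit", "sample", "channel"),
    layout = "column_major",
    dtype = "float32",
    units = "uV",
    sampling_rate = templates$sampling_rate,
    unit_positions = as.list(templates$unit_positions),
    probe = list(
      channel_ids = templates$probe$channel_id,
      x = templates$probe$x,
      y = templates$probe$y,
      pitch_x = attr(templates$probe, "pitch_x"),
      pitch_y = attr(templates$probe, "pitch_y"),
      n_columns = attr(templates$probe, "n_columns")
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = "numeric", n = prod(d), size = 4, endian = "little")
  probe <- tibble::tibble(
    channel_id = as.integer(meta$probe$channel_ids),
    x = as.numeric(meta$probe$x),
    y = as.numeric(meta$probe$y)
  )
  attr(probe, "pitch_x") <- meta$probe$pitch_x
  attr(probe, "pitch_y") <- meta$probe$pitch_y
  attr(probe, "n_columns") <- meta$probe$n_columns
  class(probe) <- c("probe_layout", class(probe))
  structure(
    list(
      waveforms = array(vals, dim = d),
      sampling_rate = meta$sampling_rate,
      unit_positions = tibble::as_tibble(meta$unit_positions),
      probe = probe
    ),
    class = "template_set"
  )
}
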
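#' Build a multi-column hexagonal probe layout
#'
#' Generates channel positions for a linear silicon probe with `n_columns`
#' columns and hexagonal staggering: columns are `pitch_x` apart, contacts
#' within a column are `pitch_y` apart, and odd columns are shifted by
#' `pitch_y / 2`. The default call reproduces a 32-channel, 3-column layout
#' with 18 um x-pitch and 22 um y-pitch, a common poly-3 commercial design.
#'
#' Channels are distributed over columns as evenly as possible (column sizes
#' differ by at most one; earlier columns take the remainder) and numbered
#' column-major starting at 1.
#'
#' @param n_channels Total number of channels.
#' @param n_columns Number of columns.
#' @param pitch_x Horizontal distance between columns (um).
#' @param pitch_y Vertical distance between contacts within a column (um).
#'
#' @return A tibble of class `probe_layout` with columns `channel_id`, `x`,
#'   `y` (um) and attributes `pitch_x`, `pitch_y`, `n_columns`.
#' @examples
#' probe <- make_probe()
#' nrow(probe)
#' @export
make_probe <- function(n_channels = 32, n_columns = 3, pitch_x = 18, pitch_y = 22) {
  check_positive(n_channels, "n_channels")
  check_positive(n_columns, "n_columns")
  check_positive(pitch_x, "pitch_x")
  check_positive(pitch_y, "pitch_y")
  if (n_columns > n_channels) {
    abort_config("`n_columns` cannot exceed `n_channels`.")
  }
  n_channels <- as.integer(n_channels)
  n_columns <- as.integer(n_columns)

  base <- n_channels %/% n_columns
  extra <- n_channels %% n_columns
  col_sizes <- rep(base, n_columns) + c(rep(1L, extra), rep(0L, n_columns - extra))

  col_idx <- rep(seq_len(n_columns) - 1L, col_sizes)
  row_idx <- unlist(lapply(col_sizes, function(k) seq_len(k) - 1L), use.names = FALSE)

  x <- col_idx * pitch_x
  y <- row_idx * pitch_y + ifelse(col_idx %% 2L == 1L, pitch_y / 2, 0)

  probe <- tibble::tibble(
    channel_id = seq_len(n_channels),
    x = x,
    y = y
  )
  attr(probe, "pitch_x") <- pitch_x
  attr(probe, "pitch_y") <- pitch_y
  attr(probe, "n_columns") <- n_columns
  class(probe) <- c("probe_layout", class(probe))
  probe
}

#' Write / read a probe layout as PRB-style JSON
#'
#' The on-disk format is a flat JSON object with `channel_ids`,
#' `positions_um` (one `[x, y]` pair per channel), `pitch` (`x`, `y`) and
#' `n_columns`.
#'
#' @param probe A `probe_layout` (see [make_probe()]).
#' @param path File path.
#' @return `write_probe()` returns `path` invisibly; `read_probe()` returns a
#'   `probe_layout` tibble.
#' @export
write_probe <- function(probe, path) {
  stopifnot(inherits(probe, "probe_layout"))
  obj <- list(
    channel_ids = probe$channel_id,
    positions_um = unname(lapply(seq_len(nrow(probe)), function(i) c(probe$x[i], probe$y[i]))),
    pitch = list(x = attr(probe, "pitch_x"), y = attr(probe, "pitch_y")),
    n_columns = attr(probe, "n_columns")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe
#' @export
read_probe <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- obj$positions_um
  if (is.list(pos)) pos <- do.call(rbind, pos)
  probe <- tibble::tibble(
    channel_id = as.integer(obj$channel_ids),
    x = as.numeric(pos[, 1]),
    y = as.numeric(pos[, 2])
  )
  attr(probe, "pitch_x") <- as.numeric(obj$pitch$x)
  attr(probe, "pitch_y") <- as.numeric(obj$pitch$y)
  attr(probe, "n_columns") <- as.integer(obj$n_columns)
  class(probe) <- c("probe_layout", class(probe))
  probe
}
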
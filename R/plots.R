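#' Plot a probe layout
#'
#' @param probe A `probe_layout`.
#' @return A ggplot object showing channel positions.
#' @export
plot_probe <- function(probe) {
  ggplot2::ggplot(probe, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 21, size = 3, fill = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.collision_profile_pooled <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    sim_band = sprintf("[%.1f, %.1f]", .data$sim_lo, .data$sim_hi)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$recall,
                                   colour = .data$sim_band)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "lag (ms)", y = "collision recall",
                  colour = "cosine similarity") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.ccg_error_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms,
                                       y = 100 * .data$mean_relative_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "CCG relative error (%)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.gt_comparison <- function(object, ...) {
  s <- unclass(object$agreement)
  df <- tidyr::expand_grid(
    gt_unit = seq_len(nrow(s)),
    sorted_unit = seq_len(ncol(s))
  )
  df$score <- s[cbind(df$gt_unit, df$sorted_unit)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sorted_unit, y = .data$gt_unit,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "sorted unit", y = "ground-truth unit",
                  fill = "agreement") +
    ggplot2::theme_minimal()
}
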
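#' Plot condition-cell summaries
#'
#' Proportion of bright responses as a function of coloration level, split by
#' previous-trial class (color) and global context (facet), with bootstrap
#' confidence intervals where available.
#'
#' @param summaries a `condition_summary` tibble.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summaries) {
  s <- summaries[!is.na(summaries$p_bright), ]
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$coloration,
                                       y = .data$p_bright,
                                       colour = .data$prev_class,
                                       group = .data$prev_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2)
  if (any(is.finite(s$ci_lo))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      width = 0.05, colour = "black", linewidth = 0.3)
  }
  if (length(unique(s$context)) > 1) {
    p <- p + ggplot2::facet_wrap(~context)
  }
  p + ggplot2::scale_colour_manual(
    values = c(prev_dull = "#1f3f77", prev_bright = "#7fb2e5"),
    name = "previous trial") +
    ggplot2::labs(x = "coloration level", y = "p(bright)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a smoothed response trajectory on a log trial axis
#'
#' @param trajectory output of [response_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  t <- trajectory[!is.na(trajectory$p_smooth), ]
  ggplot2::ggplot(t, ggplot2::aes(x = .data$index_n, y = .data$p_smooth,
                                  colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "trial index (log)", y = "p(bright), smoothed") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' RMS error versus integration length
#'
#' @param object a `brightness_eval` object.
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.brightness_eval <- function(object, ...) {
  ggplot2::ggplot(object$rms_by_L, ggplot2::aes(x = .data$L, y = .data$rms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_L, linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = object$rms_by_L$L) +
    ggplot2::labs(x = "integration length L (s)", y = "pooled RMS error",
                  title = sprintf("%s model", object$model_type)) +
    ggplot2::theme_minimal()
}
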
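#' Index plot of an influence measure
#'
#' Stem plot of one diagnostic against observation number, with the flagging
#' cutoff drawn as a horizontal rule and flagged observations highlighted and
#' labelled. For DFFITS the absolute value is plotted (the statistic is
#' flagged on \eqn{|\cdot|}).
#'
#' @param object An `influence_tbl` from [influence_table()] or [diagnose()].
#' @param measure One of `"cook"`, `"delta_chisq"`, `"delta_dev"`, `"dffits"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot influence_tbl
#' @export
autoplot.influence_tbl <- function(object,
                                   measure = c("cook", "delta_chisq",
                                               "delta_dev", "dffits"),
                                   ...) {
  measure <- match.arg(measure)
  cutoff <- attr(object, "cutoffs")[[measure]]
  flag_col <- paste0("flag_", measure)
  value <- if (measure == "dffits") abs(object[[measure]]) else object[[measure]]
  df <- tibble::tibble(
    obs = object$obs,
    value = value,
    flagged = object[[flag_col]]
  )
  ylab <- switch(measure,
    cook = "Cook's distance",
    delta_chisq = expression(Delta * chi^2),
    delta_dev = expression(Delta * d^2),
    dffits = "|DFFITS|"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$obs, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$obs, yend = 0),
                          colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 2) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_text(
      data = df[df$flagged, , drop = FALSE],
      ggplot2::aes(label = .data$obs), vjust = -0.8, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = "observation",
      y = ylab,
      title = sprintf("%s (%s estimator)", measure, attr(object, "estimator")),
      subtitle = sprintf("cutoff %.4g", cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Write an index plot to a file
#'
#' Convenience wrapper around [autoplot.influence_tbl()] + [ggplot2::ggsave()].
#'
#' @param table An `influence_tbl`.
#' @param measure Diagnostic to plot, see [autoplot.influence_tbl()].
#' @param file Output path (extension selects the device); if `NULL`, the plot
#'   is returned without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_influence <- function(table, measure = "cook", file = NULL,
                           width = 7, height = 4) {
  p <- autoplot(table, measure = measure)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Detection-rate profiles across a simulation grid
#'
#' Plots detection percentage against sample size, one line per measure,
#' faceted by collinearity level and coloured by estimator.
#'
#' @param grid A tibble from [run_grid()] (wide format).
#' @return A ggplot object.
#' @export
plot_detection <- function(grid) {
  long <- detection_long(grid)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$detection,
                                     colour = .data$estimator,
                                     linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~rho2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = "detection (%)",
                  colour = "estimator", linetype = "measure") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
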
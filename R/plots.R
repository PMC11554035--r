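#' Plot a suite result
#'
#' Grouped bar chart of mean scores per detector and regime, one facet per
#' metric, with standard-deviation error bars. Cells significantly above the
#' threshold carry an asterisk; invalid cells (fewer than `min_n` scores)
#' are marked `n < min_n`.
#'
#' @param result A `suite_result` from [run_suite()].
#' @param metric Metrics to show (default: all present).
#' @return A ggplot object.
#' @export
plot_suite <- function(result, metric = NULL) {
  stopifnot(inherits(result, "suite_result"))
  df <- suite_table(result)
  if (!is.null(metric)) df <- df[df$metric %in% metric, , drop = FALSE]
  if (nrow(df) == 0L) stop("no cells to plot")
  df$regime <- factor(df$regime,
                      levels = intersect(c(noise_ladder(), "none",
                                           "unspecified"),
                                         unique(df$regime)))
  thr <- data.frame(metric = unique(df$metric))
  thr$y <- ifelse(thr$metric == "jf", 100 * result$threshold,
                  result$threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regime, y = .data$mean,
                                   fill = .data$detector)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$flag,
                   y = .data$mean + ifelse(is.na(.data$sd), 0, .data$sd)),
      position = ggplot2::position_dodge(width = 0.8), vjust = -0.4,
      size = 3) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "noise regime", y = "mean score",
                  fill = "detector") +
    ggplot2::theme_minimal()
}
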
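#' Stacked-bar plot of estimated cell fractions
#'
#' @param object A `cell_fractions` tibble from [deconvolve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_fractions
#' @export
autoplot.cell_fractions <- function(object, ...) {
  tidy.cell_fractions(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$fraction,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated fraction", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' RMSE (or R-squared) versus noise level, per method
#'
#' @param object A `benchmark_report` from [run_benchmark()].
#' @param metric `"rmse"` or `"r2"`.
#' @param ... Unused.
#' @return A ggplot object: run-mean of the metric with a ribbon of +/- 1 SD
#'   over Monte-Carlo runs.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, metric = c("rmse", "r2"), ...) {
  metric <- match.arg(metric)
  summ <- glance.benchmark_report(object)
  mcol <- paste0("mean_", metric)
  scol <- paste0("sd_", metric)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$noise_sd, y = .data[[mcol]],
                                     colour = .data$method,
                                     fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                      ymax = .data[[mcol]] + .data[[scol]]),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Noise SD (M scale)",
                  y = if (metric == "rmse") "Average RMSE" else "Average R²",
                  colour = "Method", fill = "Method") +
    ggplot2::theme_minimal()
}

#' Scatter of estimated versus true fractions
#'
#' @param est Estimated fractions (`cell_fractions`).
#' @param truth True weights (`mixture_truth`).
#' @return A ggplot object faceted by cell type, with the identity line.
#' @export
plot_estimated_vs_true <- function(est, truth) {
  e <- tidy.cell_fractions(est)
  tr <- tidy.cell_fractions(truth)
  df <- dplyr::inner_join(e, tr, by = c("sample", "cell_type"),
                          suffix = c("_est", "_true"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_true,
                                   y = .data$fraction_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "True fraction", y = "Estimated fraction") +
    ggplot2::theme_minimal()
}
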
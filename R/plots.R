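#' Scatter plot of a worker metric against mean PCC
#'
#' One point per worker with a least-squares trend line, the standard view
#' for screening a behavioral metric against the performance criterion.
#'
#' @param metrics Per-worker metrics tibble from [compute_all_metrics()].
#' @param metric Column to plot on the x axis.
#' @return A ggplot object.
#' @export
plot_metric_pcc <- function(metrics, metric = "mpil1") {
  d <- tidyr::drop_na(metrics, dplyr::all_of(c(metric, "mean_pcc")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]], y = .data$mean_pcc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = metric, y = "mean PCC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a penalized-time constant sweep
#'
#' Correlation of penalized time with mean PCC as a function of the
#' weighting constant c, with the zero line for reference; significant
#' positive points (p < 0.05), if any, are highlighted.
#'
#' @param object A `pt_sweep` from [sweep_pt_constant()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pt_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$positive_significant),
                        colour = "red", size = 1.5) +
    ggplot2::labs(x = "weighting constant c", y = "Pearson r (PT vs mean PCC)") +
    ggplot2::theme_minimal()
}

#' Plot correlation screen results
#'
#' Bar chart of Pearson r per metric, shaded by whether the correlation
#' survives Bonferroni correction.
#'
#' @param object A `metric_correlations` tibble from [correlate_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_correlations <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$r,
                                       fill = .data$passes_bonferroni)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson r vs mean PCC",
                  fill = "passes Bonferroni") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated MAE per metric subset
#'
#' @param object A `pcc_regression` from [fit_subset_regressions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcc_regression <- function(object, ...) {
  d <- object$reports
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature_subset,
                                                     .data$mae_pct),
                                  y = .data$mae_pct,
                                  fill = .data$cohort_mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cross-validated MAE (% points)",
                  fill = "cohort") +
    ggplot2::theme_minimal()
}
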
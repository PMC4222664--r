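#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an RDM
#'
#' @param object An [rdm()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rdm <- function(object, ...) {
  ids <- stimulus_ids(object)
  df <- tidyr::expand_grid(i = ids, j = ids)
  df$value <- as.vector(t(unclass(object)))
  df$i <- factor(df$i, levels = ids)
  df$j <- factor(df$j, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Bar chart of category clustering strengths
#'
#' @param object A `category_fit` or the tibble from
#'   [clustering_strength_ci()].
#' @param ... Unused.
#' @return A ggplot (error bars included when CIs are present).
#' @exportS3Method ggplot2::autoplot
autoplot.category_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "constant", ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term,
                                                      -.data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "clustering strength (beta)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Model-comparison bar chart with noise ceiling
#'
#' Plots per-model RDM correlations (tau-a) with bootstrap standard errors
#' and, when supplied, the noise-ceiling band any true model is expected to
#' fall in.
#'
#' @param scores Tibble with columns `model`, `tau`, and optionally `se`.
#' @param ceiling Optional one-row tibble with `lower` and `upper` (e.g.
#'   from [noise_ceiling()]).
#' @return A ggplot.
#' @export
plot_model_comparison <- function(scores, ceiling = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = stats::reorder(.data$model, -.data$tau),
                                    y = .data$tau))
  if (!is.null(ceiling)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = ceiling$lower, ymax = ceiling$upper,
      alpha = 0.3, fill = "grey50"
    )
  }
  p <- p + ggplot2::geom_col(fill = "grey25")
  if ("se" %in% names(scores)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$tau - .data$se, ymax = .data$tau + .data$se),
      width = 0.2
    )
  }
  p +
    ggplot2::labs(x = NULL, y = "RDM correlation (Kendall tau-a)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
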
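# ggplot2 displays for fitted forests, regime evaluations and nowcast maps.

#' @describeIn mdi_importance Bar chart of the top MDI features.
#' @param object A `mahal_forest`.
#' @param top_n Number of features shown (default 20).
#' @export
autoplot.mahal_forest <- function(object, top_n = 20, ...) {
  imp <- head(mdi_importance(object), top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$mdi,
    y = stats::reorder(.data$feature, .data$mdi)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean decrease in impurity", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_regime Metric bars per outcome and model variant.
#' @param object A `regime_evaluation`.
#' @param level Aggregation level to display (default `"aggregate"`).
#' @param metric `"r2"` or `"nrmse"`.
#' @export
autoplot.regime_evaluation <- function(object, level = "aggregate",
                                       metric = c("r2", "nrmse"), ...) {
  metric <- match.arg(metric)
  m <- object$metrics[object$metrics$level == level, ]
  if (level == "country_mean") m <- m[m$weighting == "size", ]
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$outcome, y = .data[[metric]], fill = .data$variant
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      y = if (metric == "r2") expression(r^2) else "NRMSE",
      x = NULL, fill = NULL,
      title = sprintf("%s (%s level)", object$regime, level)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a nowcast map
#'
#' Scatter of enumeration areas coloured by the predicted prevalence (or its
#' across-tree standard deviation, the uncertainty display).
#'
#' @param map Tibble from [emit_nowcast_map()] (or the `nowcast_map_*.csv`
#'   output of [run_pipeline()]).
#' @param outcome Outcome to display (default: first present).
#' @param stat `"mean"` or `"sd"`.
#' @return A ggplot object.
#' @export
plot_nowcast_map <- function(map, outcome = NULL, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  outcome <- outcome %||% map$outcome[1]
  sub <- map[map$outcome == outcome, ]
  ggplot2::ggplot(sub, ggplot2::aes(
    x = .data$lon, y = .data$lat, colour = .data[[stat]]
  )) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      colour = if (stat == "mean") "Predicted\nprevalence" else "Across-tree\nSD",
      title = outcome
    ) +
    ggplot2::theme_minimal()
}
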
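#' Gap plot of actual versus counterfactual endpoints
#'
#' One row per assessable unit: a segment from the counterfactual endpoint
#' to the achieved endpoint, facetted by indicator. Segments pointing right
#' (actual above counterfactual) are districts where mortality ended worse
#' than pre-war momentum predicted.
#'
#' @param object A `conflict_impact` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conflict_impact <- function(object, ...) {
  df <- object$classification |>
    dplyr::filter(.data$assessable) |>
    dplyr::mutate(unit_id = stats::reorder(.data$unit_id, .data$actual - .data$counterfactual))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$unit_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$counterfactual, xend = .data$actual,
                   yend = .data$unit_id, colour = .data$endpoint_flag),
      linewidth = 0.8,
      arrow = grid::arrow(length = grid::unit(4, "pt"), type = "closed")
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$counterfactual), shape = 1) +
    ggplot2::facet_wrap(~indicator, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(worse = "#b2182b", better = "#2166ac", same = "grey40",
                 not_assessable = "grey80")
    ) +
    ggplot2::labs(
      x = "deaths per 1,000 live births (o = counterfactual, arrow = achieved)",
      y = NULL, colour = "endpoint"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of the conflict impact index
#'
#' @param index An [impact_index()] tibble.
#' @return A ggplot object.
#' @export
plot_impact_index <- function(index) {
  df <- index |>
    dplyr::mutate(
      shown = ifelse(is.na(.data$weight), -1L, .data$weight),
      unit_id = stats::reorder(.data$unit_id, .data$shown)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit_id, y = .data$shown,
                                   fill = .data$weight_class)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(
      breaks = -1:4,
      labels = c("n/a", 0:4), limits = c(-1.2, 4.2)
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "conflict impact weight (0-4)",
                  fill = "impact") +
    ggplot2::theme_minimal()
}
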
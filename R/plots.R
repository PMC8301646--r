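# Plot methods for the tabular result types.

#' Index heatmap
#'
#' Traits x treatments heatmap of drought indices: green cells (index at
#' or above 1) mean the trait was unaffected or improved under the
#' treatment, orange-to-red cells (below 1) that it was depressed.
#'
#' @param object An [index_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot index_table
#' @export
autoplot.index_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$treatment, y = .data$index,
                                       fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "orange",
                                  high = "forestgreen", midpoint = 0.75) +
    ggplot2::labs(title = "Drought indices by treatment", fill = "index") +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param object A [pearson_matrix()] result.
#' @param ... Unused.
#' @return A ggplot tile map of r with significance stars.
#' @method autoplot pearson_matrix
#' @export
autoplot.pearson_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$var1, y = .data$var2,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "x",
                     paste0(sprintf("%.2f", .data$r), .data$stars))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(title = "Pearson correlations", fill = "r") +
    ggplot2::theme_minimal()
}

#' Watering-plan plot
#'
#' @param object A [treatment_schedule()] plan.
#' @param ... Unused.
#' @return A ggplot of daily target pot weight coloured by phase.
#' @method autoplot watering_plan
#' @export
autoplot.watering_plan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$target,
                                       colour = .data$phase)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days after sowing", y = "target pot weight (g)",
                  title = paste("Watering schedule:", attr(object, "treatment"))) +
    ggplot2::theme_minimal()
}

#' Growth-series plot
#'
#' @param series A [generate_growth_series()] tibble.
#' @return A ggplot of mean ESB vs day per treatment.
#' @export
plot_growth_series <- function(series) {
  avg <- series |>
    group_by(.data$treatment, .data$day) |>
    summarise(esb = mean(.data$esb), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$day, y = .data$esb,
                                    colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days after sowing", y = "ESB (kilopixels)",
                  title = "Dynamic growth curves by treatment") +
    ggplot2::theme_minimal()
}
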
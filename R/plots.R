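#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation heatmap of imaging features vs functional outcomes
#'
#' Tile plot of Pearson r, features on the y-axis and outcomes on the
#' x-axis, diverging colour scale centred at 0; excluded cells are blank.
#'
#' @param object An `lt_heatmap` tibble from [correlate_outcomes()].
#' @param label_r Print r values in the tiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lt_heatmap <- function(object, label_r = TRUE, ...) {
  df <- dplyr::filter(object, .data$included)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome,
                                        y = .data$feature,
                                        fill = .data$r)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Imaging features vs outcomes, day %g",
                                  unique(object$outcome_timepoint_day)[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (label_r) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                             .data$r)),
                                size = 3)
  }
  p
}

#' Bar chart of top lesioned structures
#'
#' Cohort-mean PoS or PoL (with SD error bars) for the ranked structures.
#'
#' @param ranking Output of [rank_structures()].
#' @param score_label Axis label.
#' @return A ggplot object.
#' @export
plot_structure_ranking <- function(ranking,
                                   score_label = "Percent of structure (%)") {
  df <- dplyr::mutate(ranking, structure_name = stats::reorder(
    .data$structure_name, .data$mean_score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_score,
                                   y = .data$structure_name)) +
    ggplot2::geom_col(fill = "#B2182B", alpha = 0.8) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = pmax(.data$mean_score - .data$sd_score, 0),
      xmax = pmin(.data$mean_score + .data$sd_score, 100)),
      height = 0.25) +
    ggplot2::labs(x = score_label, y = NULL) +
    ggplot2::theme_minimal()
}
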
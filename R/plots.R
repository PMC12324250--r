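# ggplot2 helpers for the main result types.

#' Volcano plot of strain-level modifier results
#'
#' Area between curves on the x axis, -log10 of the smallest Holm-adjusted
#' p-value on the y axis; enhancers (worse climbing) left, suppressors
#' right.
#'
#' @param strain_results Tibble from [analyze_strain()] rows (needs `area`,
#'   the `*_adj` columns and `call`).
#' @return A ggplot object.
#' @export
plot_modifier_volcano <- function(strain_results) {
  assert_cols(strain_results, c("area", "p_genotype_adj", "p_additive_adj",
                                "p_interactive_adj", "call"),
              "strain_results")
  d <- strain_results |>
    mutate(p_min = pmin(.data$p_genotype_adj, .data$p_additive_adj,
                        .data$p_interactive_adj),
           neglog_p = -log10(pmax(.data$p_min, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area, y = .data$neglog_p,
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(enhancer = "darkorange",
                                            suppressor = "forestgreen",
                                            none = "mediumpurple")) +
    ggplot2::labs(x = "area between curves (mm/s · day)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Heatmap of row-centered oligogenic scores
#'
#' Individuals (ordered by the chosen principal-component projection) as
#' rows, phenotype clusters as columns.
#'
#' @param heatmap Tibble from [center_rows()].
#' @param subgroups Optional tibble `individual_id`, `subgroup` used for a
#'   row annotation strip.
#' @return A ggplot object.
#' @export
plot_risk_heatmap <- function(heatmap, subgroups = NULL) {
  assert_cols(heatmap, "individual_id", "heatmap")
  d <- heatmap |>
    mutate(individual_id = factor(.data$individual_id,
                                  levels = rev(.data$individual_id))) |>
    tidyr::pivot_longer(-"individual_id", names_to = "cluster",
                        values_to = "score")
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster,
                                       y = .data$individual_id,
                                       fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  g
}

#' Plot an ERG trace
#'
#' @param object An `erg_trace`.
#' @param ... Unused.
#' @return A ggplot object with the stimulus window shaded.
#' @export
autoplot.erg_trace <- function(object, ...) {
  onset <- attr(object, "stimulus_onset")
  offset <- attr(object, "stimulus_offset")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$voltage_mv)) +
    ggplot2::annotate("rect", xmin = onset, xmax = offset, ymin = -Inf,
                      ymax = Inf, alpha = 0.12, fill = "gold") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
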
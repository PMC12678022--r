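# ggplot2 views of tissues, niches, marker tables and boundary profiles.

#' Plot cells in tissue coordinates
#'
#' Scatter of cell centroids in image convention (y increasing downward),
#' coloured by any cell-level column (cell type, niche, cluster, ...).
#'
#' @param cells Cell metadata tibble with `x_um`, `y_um`.
#' @param colour Column to colour by (tidy-eval), default `cell_type`.
#' @param point_size Point size.
#' @return A ggplot.
#' @export
plot_tissue <- function(cells, colour = cell_type, point_size = 0.6) {
  ggplot2::ggplot(cells, ggplot2::aes(.data$x_um, .data$y_um,
                                      colour = {{ colour }})) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm, depth)") +
    ggplot2::theme_minimal()
}

#' Stacked composition bars for niche summaries
#'
#' @param summary One of the two tibbles returned by [niche_summary()].
#' @return A ggplot.
#' @export
plot_niche_composition <- function(summary) {
  if ("cell_type" %in% names(summary)) {
    ggplot2::ggplot(summary, ggplot2::aes(factor(.data$niche),
                                          .data$proportion,
                                          fill = .data$cell_type)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "niche", y = "proportion of cells",
                    fill = "cell type") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(summary, ggplot2::aes(.data$condition, .data$proportion,
                                          fill = factor(.data$niche))) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "condition", y = "proportion of cells",
                    fill = "niche") +
      ggplot2::theme_minimal()
  }
}

#' Volcano plot of a marker table
#'
#' @param object A `marker_table` from [rank_markers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot marker_table
#' @export
autoplot.marker_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log2_fc,
                                       -log10(pmax(.data$p_adj, 1e-300)),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Expression-vs-depth profile plot
#'
#' @param object A `boundary_profile` from [boundary_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boundary_profile
#' @export
autoplot.boundary_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$distance_mid_um,
                                       .data$mean_expression)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "distance from epidermis (µm)",
      y = "mean normalized expression",
      title = sprintf("%s (Spearman trend ρ = %.2f)",
                      attr(object, "gene"), attr(object, "trend_rho"))
    ) +
    ggplot2::theme_minimal()
}

#' BIC curve across candidate niche numbers
#'
#' @param model A `niche_model` or `niche_fit`.
#' @return A ggplot of BIC against G with the selected model highlighted.
#' @export
plot_bic <- function(model) {
  if (inherits(model, "niche_fit")) model <- model$model
  tab <- model$bic_table
  ggplot2::ggplot(tab, ggplot2::aes(.data$G, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tab[tab$G == model$selected_G, ],
                        colour = "firebrick", size = 3) +
    ggplot2::labs(x = "number of niches (G)", y = "BIC (lower is better)") +
    ggplot2::theme_minimal()
}
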
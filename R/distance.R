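# Distance-to-cell-type maps and distance-conditioned differential
# expression: the proximal/distal fibroblast analyses.

#' Distance from every cell to the nearest cell of a target type
#'
#' Euclidean centroid distance, computed within each sample (cross-sample
#' distances are physically meaningless). Samples containing no target
#' cells get `Inf` distances and are flagged.
#'
#' @param cells Annotated cell metadata (`cell_id`, `x_um`, `y_um`,
#'   `sample_id`, `cell_type`).
#' @param target_type Cell-type label of the target population.
#' @return A tibble of class `distance_map`: `cell_id`, `sample_id`,
#'   `distance_um` (`Inf` where undefined), `defined` (logical); attribute
#'   `target_type`.
#' @export
distance_to_nearest <- function(cells, target_type) {
  if (!target_type %in% cells$cell_type) {
    abort(sprintf("unknown target cell type '%s'", target_type))
  }
  out <- cells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      xy <- cbind(df$x_um, df$y_um)
      targ <- xy[df$cell_type == target_type, , drop = FALSE]
      d <- nearest_distance(xy, targ)
      # a target cell's own nearest target is itself at distance 0, which is
      # what "distance to nearest neutrophil" means for a neutrophil
      tibble(cell_id = df$cell_id, sample_id = key$sample_id,
             distance_um = d, defined = is.finite(d))
    }) |>
    dplyr::bind_rows()
  out <- out[match(cells$cell_id, out$cell_id), ]
  structure(out, target_type = target_type,
            class = c("distance_map", class(out)))
}

#' Differential expression between distance-proximal and distance-distal cells
#'
#' Selects the query-type cells closer than `proximal_max` to the target
#' (group A) and farther than `distal_min` (group B), drops the
#' intermediate cells, and delegates to [rank_markers()]. Positive
#' `log2_fc` means proximal-elevated. The default 30/300 um bins are the
#' figure-legend thresholds; the 10/50 um pair also printed in the source
#' results text is available as `distance_bins("narrow")`.
#'
#' @param counts A normalized [count_matrix()].
#' @param cells Annotated cell metadata.
#' @param dmap A `distance_map` from [distance_to_nearest()].
#' @param query_type Cell type whose expression is compared (e.g.
#'   fibroblasts).
#' @param bins A [distance_bins()] pair.
#' @param min_pct,lfc_threshold Passed to [rank_markers()].
#' @return A `marker_table` (group label `"proximal"`).
#' @export
proximal_distal_de <- function(counts, cells, dmap, query_type,
                               bins = distance_bins(), min_pct = 0.25,
                               lfc_threshold = 0.2) {
  q <- cells$cell_type == query_type
  d <- dmap$distance_um[match(cells$cell_id, dmap$cell_id)]
  prox <- cells$cell_id[q & d < bins$proximal_max]
  dist <- cells$cell_id[q & d > bins$distal_min & is.finite(d)]
  if (length(prox) < 3L || length(dist) < 3L) {
    abort(sprintf(
      "need at least 3 %s cells per distance bin; got %d proximal (< %g um) and %d distal (> %g um)",
      query_type, length(prox), bins$proximal_max, length(dist), bins$distal_min))
  }
  rank_markers(counts, prox, dist, min_pct = min_pct,
               lfc_threshold = lfc_threshold, group_label = "proximal")
}

#' Proximal/distal distance thresholds
#'
#' @param preset `"default"` (< 30 um proximal, > 300 um distal) or
#'   `"narrow"` (< 10 um, > 50 um).
#' @param proximal_max,distal_min Explicit thresholds overriding the preset.
#' @return List with `proximal_max` and `distal_min` (micrometres).
#' @export
distance_bins <- function(preset = c("default", "narrow"),
                          proximal_max = NULL, distal_min = NULL) {
  preset <- match.arg(preset)
  out <- switch(preset,
                default = list(proximal_max = 30, distal_min = 300),
                narrow = list(proximal_max = 10, distal_min = 50))
  if (!is.null(proximal_max)) out$proximal_max <- proximal_max
  if (!is.null(distal_min)) out$distal_min <- distal_min
  if (!(out$proximal_max > 0 && out$proximal_max < out$distal_min)) {
    abort("need 0 < proximal_max < distal_min")
  }
  out
}

#' Rank genes by correlation of expression with target distance
#'
#' Spearman correlation between each gene's normalized expression and the
#' distance to the nearest target cell, across query-type cells with
#' defined distances. Genes are ranked ascending: the most negative
#' correlations (proximal-biased genes) come first. Genes constant across
#' the query cells get correlation 0 and are flagged.
#'
#' @inheritParams proximal_distal_de
#' @return Tibble `gene`, `rho`, `rank`, `constant`, ordered by `rho`.
#' @export
distance_correlation_rank <- function(counts, cells, dmap, query_type) {
  need_normalized(counts, "distance_correlation_rank")
  d_all <- dmap$distance_um[match(cells$cell_id, dmap$cell_id)]
  q <- cells$cell_type == query_type & is.finite(d_all)
  if (sum(q) < 10L) {
    abort(sprintf("need at least 10 %s cells with defined distances, got %d",
                  query_type, sum(q)))
  }
  idx <- match(cells$cell_id[q], cells_of(counts))
  x <- as.matrix(counts$normalized[, idx, drop = FALSE])
  d <- d_all[q]
  rho <- apply(x, 1L, spearman_safe, y = d)
  constant <- is.na(rho)
  rho[constant] <- 0
  out <- tibble(gene = genes_of(counts), rho = unname(rho),
                constant = unname(constant)) |>
    dplyr::arrange(.data$rho) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Expression profile as a function of distance from the epidermis
#'
#' Bins cells into `n_bins` equal-width bins of distance from the epidermal
#' boundary line (`|y - epidermis_depth_um|`) and reports the mean
#' normalized expression of one gene per bin, plus the Spearman trend of
#' expression against boundary distance over individual cells.
#'
#' @param counts A normalized [count_matrix()].
#' @param cells Cell metadata (`cell_id`, `y_um`).
#' @param gene Gene name.
#' @param n_bins Number of equal-width distance bins (default 20).
#' @param epidermis_depth_um Depth of the epidermal boundary line.
#' @return A tibble of class `boundary_profile`: `bin`, `distance_mid_um`,
#'   `mean_expression`, `n_cells`; attributes `trend_rho` and `gene`.
#' @export
boundary_profile <- function(counts, cells, gene, n_bins = 20L,
                             epidermis_depth_um) {
  need_normalized(counts, "boundary_profile")
  if (!gene %in% genes_of(counts)) abort(sprintf("unknown gene '%s'", gene))
  idx <- match(cells$cell_id, cells_of(counts))
  if (anyNA(idx)) abort("cells missing from the count matrix")
  expr <- as.numeric(counts$normalized[gene, idx])
  d <- epidermis_distance(cells$y_um, epidermis_depth_um)
  breaks <- seq(0, max(d) + 1e-9, length.out = n_bins + 1L)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  prof <- tibble(bin = bin, d = d, expr = expr) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_expression = mean(.data$expr),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(distance_mid_um = (breaks[.data$bin] + breaks[.data$bin + 1L]) / 2) |>
    dplyr::select("bin", "distance_mid_um", "mean_expression", "n_cells")
  trend <- spearman_safe(expr, d)
  structure(prof, trend_rho = if (is.na(trend)) 0 else trend, gene = gene,
            class = c("boundary_profile", class(prof)))
}
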
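# broom-style tidiers for fitted objects.

#' Tidy a niche mixture model
#'
#' One row per niche and cell type, with the component mean composition,
#' variance and mixture weight.
#'
#' @param x A `niche_model` (from [fit_niches()], element `model`).
#' @param ... Unused.
#' @return Tibble `niche`, `cell_type`, `mean`, `variance`, `weight`.
#' @method tidy niche_model
#' @export
tidy.niche_model <- function(x, ...) {
  G <- nrow(x$means)
  purrr::map_dfr(seq_len(G), function(g) {
    tibble(
      niche = g,
      cell_type = x$types,
      mean = x$means[g, ],
      variance = x$vars[g, ],
      weight = x$weights[g]
    )
  })
}

#' One-line summary of a niche mixture model
#'
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return Tibble with `selected_G`, `bic`, `loglik`, `n_models_compared`.
#' @method glance niche_model
#' @export
glance.niche_model <- function(x, ...) {
  tibble(
    selected_G = x$selected_G,
    bic = x$bic_table$bic[x$bic_table$G == x$selected_G],
    loglik = x$loglik,
    n_models_compared = nrow(x$bic_table)
  )
}

#' @rdname tidy.niche_model
#' @method tidy niche_fit
#' @export
tidy.niche_fit <- function(x, ...) tidy.niche_model(x$model, ...)

#' @rdname glance.niche_model
#' @method glance niche_fit
#' @export
glance.niche_fit <- function(x, ...) glance.niche_model(x$model, ...)

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-cell assignment tibble (`cell_id`, `cluster`).
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$assignment

#' @rdname tidy.cluster_result
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    n_cells = nrow(x$assignment),
    n_clusters = length(unique(x$assignment$cluster)),
    resolution = x$params$resolution,
    n_neighbors = x$params$n_neighbors
  )
}
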
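# Dimensionality reduction, graph clustering, and cluster annotation.

#' Principal-component reduction of the normalized matrix
#'
#' Standardizes each gene of the normalized layer (unit variance across
#' cells; constant genes are left centred at zero) and returns the top
#' `n_pcs` principal-component scores per cell. Deterministic up to
#' component sign.
#'
#' @param counts A normalized [count_matrix()].
#' @param n_pcs Number of components; must not exceed
#'   `min(n_genes, n_cells) - 1`.
#' @return A cells-by-`n_pcs` numeric matrix with `cell_id` rownames and the
#'   proportion of variance explained in `attr(, "var_explained")`.
#' @export
reduce_pca <- function(counts, n_pcs = 50L) {
  need_normalized(counts, "reduce_pca")
  x <- Matrix::t(counts$normalized)  # cells x genes
  lim <- min(dim(x)) - 1L
  if (n_pcs > lim) {
    abort(sprintf("n_pcs = %d exceeds min(genes, cells) - 1 = %d", n_pcs, lim))
  }
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  sdev[sdev == 0] <- 1
  x <- sweep(sweep(x, 2L, mu), 2L, sdev, `/`)
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- cells_of(counts)
  attr(scores, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]
  scores
}

# k nearest neighbours (excluding self) by Euclidean distance, blocked.
knn_indices <- function(x, k, block = 512L) {
  n <- nrow(x)
  if (k >= n) abort(sprintf("need more cells (%d) than neighbors (k = %d)", n, k))
  idx <- matrix(0L, n, k)
  for (i0 in seq(1L, n, by = block)) {
    rows <- i0:min(i0 + block - 1L, n)
    d <- dist_block(x[rows, , drop = FALSE], x)
    d[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    idx[rows, ] <- t(apply(d, 1L, function(v) order(v)[seq_len(k)]))
  }
  idx
}

# Shared-nearest-neighbor graph with Jaccard-style weights
# shared / (2k - shared), pruned below `prune`.
snn_graph <- function(embedding, k, prune = 1 / 15) {
  n <- nrow(embedding)
  nn <- knn_indices(embedding, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])
  sel <- w >= prune
  g <- igraph::graph_from_edgelist(cbind(i[sel], j[sel]), directed = FALSE)
  igraph::E(g)$weight <- w[sel]
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Leiden clustering on a shared-nearest-neighbor graph
#'
#' Builds a k-shared-nearest-neighbor graph on the embedding (Euclidean in
#' PC space, Jaccard-style edge weights) and partitions it with the Leiden
#' algorithm under the modularity objective at the given resolution.
#' Cluster labels are renumbered by decreasing cluster size, so label 1 is
#' always the largest cluster; the run is deterministic given `seed`.
#'
#' @param embedding Cells-by-dimensions matrix from [reduce_pca()] (rownames
#'   are cell ids).
#' @param resolution Leiden resolution (default 0.4).
#' @param n_neighbors Neighbors per cell for the graph (default 20).
#' @param seed Integer seed for the Leiden refinement.
#' @return An object of class `cluster_result`: list with `assignment`
#'   (tibble `cell_id`, `cluster`), `embedding`, and `params`.
#' @export
cluster_cells <- function(embedding, resolution = 0.4, n_neighbors = 20L,
                          seed = 1L) {
  if (!all(is.finite(embedding))) abort("embedding must be finite")
  g <- snn_graph(embedding, k = n_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 10L
  )
  member <- igraph::membership(comm)
  sizes <- sort(table(member), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cluster <- as.integer(relabel[as.character(member)])
  structure(
    list(
      assignment = tibble(cell_id = rownames(embedding), cluster = cluster),
      embedding = embedding,
      params = list(n_pcs = ncol(embedding), resolution = resolution,
                    n_neighbors = n_neighbors, seed = seed)
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cells in %d clusters (resolution %.2f, k = %d)\n",
              nrow(x$assignment), length(unique(x$assignment$cluster)),
              x$params$resolution, x$params$n_neighbors))
  invisible(x)
}

#' Annotate clusters from a marker-gene dictionary
#'
#' Assigns each cluster the label whose marker genes have the highest mean
#' normalized expression averaged over the cluster's cells. Records the
#' runner-up label and margin; exact ties are broken alphabetically and
#' flagged. Clusters where every label scores zero are labelled
#' `"unassigned"`. Marker genes absent from the matrix are dropped with a
#' warning.
#'
#' @param clusters A `cluster_result` from [cluster_cells()], or a tibble
#'   with `cell_id` and `cluster` columns.
#' @param counts A normalized [count_matrix()].
#' @param marker_dict Named list mapping cell-type label to a character
#'   vector of marker genes.
#' @return An object of class `annotation_map`: tibble `cluster`, `label`,
#'   `score`, `runner_up`, `margin`, `tie`.
#' @export
annotate_clusters <- function(clusters, counts, marker_dict) {
  need_normalized(counts, "annotate_clusters")
  if (length(marker_dict) == 0L) abort("marker_dict must contain at least one label")
  assignment <- if (inherits(clusters, "cluster_result")) clusters$assignment else as_tibble(clusters)
  genes <- genes_of(counts)
  dict <- purrr::imap(marker_dict, function(gs, lab) {
    missing <- setdiff(gs, genes)
    if (length(missing)) {
      warn(sprintf("label '%s': marker genes not in matrix, ignored: %s",
                   lab, paste(missing, collapse = ", ")))
    }
    intersect(gs, genes)
  })
  dict <- dict[lengths(dict) > 0]
  if (length(dict) == 0L) abort("no marker genes matched the gene index")

  idx <- match(assignment$cell_id, cells_of(counts))
  if (anyNA(idx)) abort("cluster assignment lists cells missing from the count matrix")
  # per-label mean marker expression per cell
  label_scores <- vapply(dict, function(gs) {
    Matrix::colMeans(counts$normalized[gs, idx, drop = FALSE])
  }, numeric(nrow(assignment)))
  label_scores <- matrix(label_scores, ncol = length(dict),
                         dimnames = list(NULL, names(dict)))
  out <- purrr::map_dfr(sort(unique(assignment$cluster)), function(cl) {
    sc <- colMeans(label_scores[assignment$cluster == cl, , drop = FALSE])
    ord <- order(-sc, names(sc))  # alphabetical tie-break
    best <- names(sc)[ord[1]]
    tie <- length(sc) > 1 && sc[ord[1]] == sc[ord[2]]
    tibble(
      cluster = cl,
      label = if (sc[ord[1]] == 0) "unassigned" else best,
      score = unname(sc[ord[1]]),
      runner_up = if (length(sc) > 1) names(sc)[ord[2]] else NA_character_,
      margin = if (length(sc) > 1) unname(sc[ord[1]] - sc[ord[2]]) else NA_real_,
      tie = tie
    )
  })
  structure(out, class = c("annotation_map", class(out)))
}

#' Attach cell-type labels to the cell table
#'
#' @param cells Cell metadata tibble.
#' @param clusters `cluster_result` or tibble with `cell_id`, `cluster`.
#' @param annotation An `annotation_map` from [annotate_clusters()].
#' @return `cells` with `cluster` and `cell_type` columns filled in.
#' @export
label_cells <- function(cells, clusters, annotation) {
  assignment <- if (inherits(clusters, "cluster_result")) clusters$assignment else as_tibble(clusters)
  cells |>
    dplyr::left_join(assignment, by = "cell_id") |>
    dplyr::left_join(dplyr::select(annotation, "cluster", cell_type = "label"),
                     by = "cluster")
}
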
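# Gene-set module scoring with expression-matched binned controls, and the
# simpler marker-mean score used for deconvolution-style summaries.

#' Gene-set module score with binned control genes
#'
#' Ranks all genes by their dataset-average normalized expression, cuts the
#' ranking into `n_bins` equal-size bins, and for every gene-set gene draws
#' up to `n_ctrl` control genes without replacement from the gene's bin
#' (excluding gene-set members whenever the bin contains any other gene).
#' The score of a cell is the mean normalized expression over the set genes
#' minus the mean over the pooled control genes, so a score of zero means
#' "no different from expression-matched background". Control sampling is
#' seeded and therefore reproducible.
#'
#' @param counts A normalized [count_matrix()].
#' @param gene_set Character vector of gene names (or a list with elements
#'   `name` and `genes`).
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes per set gene (default 100; capped at the bin
#'   size).
#' @param seed Integer seed for control sampling.
#' @param name Score name used in the output column.
#' @return Tibble `cell_id`, `score` (one row per cell); attribute
#'   `control_genes`.
#' @export
module_score <- function(counts, gene_set, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L, name = "score") {
  need_normalized(counts, "module_score")
  if (is.list(gene_set) && !is.null(gene_set$genes)) {
    name <- gene_set$name %||% name
    gene_set <- gene_set$genes
  }
  genes <- genes_of(counts)
  set_genes <- sort(intersect(gene_set, genes))  # order-invariant scoring
  if (length(set_genes) == 0L) {
    abort("gene set does not intersect the gene index")
  }
  n_bins <- min(n_bins, length(genes))
  avg <- Matrix::rowMeans(counts$normalized)
  # equal-size bins over the expression ranking; ties broken by name order
  # for determinism
  ord <- order(avg, genes)
  bin_of <- integer(length(genes))
  bin_of[ord] <- ceiling(seq_along(genes) / (length(genes) / n_bins))
  names(bin_of) <- genes

  set.seed(seed)
  ctrl <- unlist(lapply(set_genes, function(g) {
    mates <- genes[bin_of == bin_of[[g]]]
    pool <- setdiff(mates, gene_set)
    if (length(pool) == 0L) pool <- mates  # set covers the bin: controls = bin
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  }))
  ctrl <- unique(ctrl)
  set_mean <- Matrix::colMeans(counts$normalized[set_genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(counts$normalized[ctrl, , drop = FALSE])
  out <- tibble(cell_id = cells_of(counts), score = unname(set_mean - ctrl_mean))
  names(out)[2] <- name
  attr(out, "control_genes") <- ctrl
  out
}

#' Per-cell marker-mean scores for a label dictionary
#'
#' For each label, the mean normalized expression of its marker genes in
#' each cell (or pseudobulk column). A deliberately simple, fully specified
#' deconvolution-style summary: no regression or machine-learning step.
#'
#' @param counts A normalized [count_matrix()].
#' @param marker_dict Named list mapping label to marker gene vector.
#' @return Tibble with `cell_id` and one numeric column per label; labels
#'   with no matching genes are skipped with a warning.
#' @export
marker_mean_score <- function(counts, marker_dict) {
  need_normalized(counts, "marker_mean_score")
  if (length(marker_dict) == 0L) abort("marker_dict must be non-empty")
  genes <- genes_of(counts)
  out <- tibble(cell_id = cells_of(counts))
  for (lab in names(marker_dict)) {
    gs <- intersect(marker_dict[[lab]], genes)
    if (length(gs) == 0L) {
      warn(sprintf("label '%s' has no marker genes in the matrix; skipped", lab))
      next
    }
    out[[lab]] <- unname(Matrix::colMeans(counts$normalized[gs, , drop = FALSE]))
  }
  if (ncol(out) == 1L) abort("no label had marker genes in the matrix")
  out
}

#' Read gene sets from a two-column table
#'
#' @param path TSV/CSV with columns `set_name` and `gene`.
#' @return Named list of gene vectors.
#' @export
read_gene_sets <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- read.delim(path, sep = sep)
  if (!all(c("set_name", "gene") %in% names(tab))) {
    abort("gene-set table needs columns 'set_name' and 'gene'")
  }
  split(as.character(tab$gene), tab$set_name)
}
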
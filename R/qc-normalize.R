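# Reading segmented spatial count data, cell-level QC, and square-root
# total-count normalization.

#' Read a spatial count dataset from disk
#'
#' Reads a genes-by-cells count matrix (MatrixMarket `.mtx`, or a dense
#' delimited table whose first column holds gene names and whose header
#' holds cell ids), a gene index (one name per line; ignored for dense
#' tables), and a cell metadata table, and aligns them.
#'
#' @param count_path Path to `.mtx` counts or a dense `.csv`/`.tsv` table.
#' @param gene_index Path to the gene index; may be `NULL` for dense tables.
#' @param metadata Path to a tab- or comma-separated cell metadata table
#'   with at least a `cell_id` column (the fixture layout also carries
#'   `x_um`, `y_um`, `area_um2`, `sample_id`, `condition`).
#' @return A list with `cells` (tibble, one row per cell, ordered as the
#'   matrix columns) and `counts` (a [count_matrix()]).
#' @export
read_dataset <- function(count_path, gene_index = NULL, metadata = NULL) {
  for (p in c(count_path, gene_index, metadata)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  ext <- tolower(tools::file_ext(count_path))
  if (ext == "mtx") {
    if (is.null(gene_index)) abort("MatrixMarket counts require a gene index file")
    first <- readLines(count_path, n = 1L)
    if (!grepl("^%%MatrixMarket\\s+matrix", first)) {
      abort(sprintf("malformed MatrixMarket header in %s: '%s'", count_path, first))
    }
    raw <- methods::as(Matrix::readMM(count_path), "CsparseMatrix")
    genes <- readLines(gene_index)
    if (length(genes) != nrow(raw)) {
      abort(sprintf("gene index has %d names but the matrix has %d rows",
                    length(genes), nrow(raw)))
    }
    rownames(raw) <- genes
  } else {
    sep <- if (ext == "csv") "," else "\t"
    tab <- read.delim(count_path, sep = sep, check.names = FALSE)
    genes <- as.character(tab[[1]])
    raw <- as.matrix(tab[, -1, drop = FALSE])
    rownames(raw) <- genes
    raw <- Matrix::Matrix(raw, sparse = TRUE)
  }
  if (is.null(metadata)) abort("a cell metadata table is required")
  sep_m <- if (tolower(tools::file_ext(metadata)) == "csv") "," else "\t"
  cells <- as_tibble(read.delim(metadata, sep = sep_m, check.names = FALSE))
  if (!"cell_id" %in% names(cells)) abort("metadata must contain a cell_id column")
  cells$cell_id <- as.character(cells$cell_id)
  if (is.null(colnames(raw))) {
    if (nrow(cells) != ncol(raw)) {
      abort(sprintf("metadata lists %d cells but the matrix has %d columns",
                    nrow(cells), ncol(raw)))
    }
    colnames(raw) <- cells$cell_id
  }
  only_meta <- setdiff(cells$cell_id, colnames(raw))
  only_mat <- setdiff(colnames(raw), cells$cell_id)
  if (length(only_meta) || length(only_mat)) {
    abort(paste0(
      "cell ids do not match between metadata and counts. ",
      if (length(only_meta)) paste0("Only in metadata: ",
                                    paste(head(only_meta, 5), collapse = ", "),
                                    if (length(only_meta) > 5) ", ...", ". ") else "",
      if (length(only_mat)) paste0("Only in counts: ",
                                   paste(head(only_mat, 5), collapse = ", "),
                                   if (length(only_mat) > 5) ", ...", ".") else ""
    ))
  }
  raw <- raw[, cells$cell_id, drop = FALSE]
  list(cells = cells, counts = count_matrix(raw))
}

#' Cell-level quality-control filter
#'
#' Removes cells with fewer than `min_counts` total transcripts, and cells
#' whose segmented area exceeds `area_fold` times the average cell area.
#' The average area is computed once over all input cells, before any
#' removal, in a single pass (no iteration); by default it is taken per
#' sample, since segmentation scale varies between slides.
#'
#' @param cells Cell metadata tibble (needs `cell_id`, `area_um2`, and
#'   `sample_id` when `area_scope = "sample"`).
#' @param counts A [count_matrix()] aligned with `cells`.
#' @param min_counts Minimum total counts per cell (default 20).
#' @param area_fold Maximum area as a multiple of the mean area (default 5).
#' @param area_scope `"sample"` (mean area per sample) or `"global"`.
#' @return A list with the filtered `cells` and `counts` plus `report`, a
#'   tibble with the number of cells failing each criterion and retained.
#' @export
qc_filter <- function(cells, counts, min_counts = 20L, area_fold = 5,
                      area_scope = c("sample", "global")) {
  area_scope <- match.arg(area_scope)
  stopifnot(min_counts >= 0, area_fold > 0)
  check_cells_aligned(cells, counts)
  n <- nrow(cells)
  if (n == 0L) {
    return(list(cells = cells, counts = counts,
                report = tibble(n_input = 0L, n_low_counts = 0L,
                                n_large_area = 0L, n_retained = 0L)))
  }
  totals <- Matrix::colSums(counts$raw)
  mean_area <- if (area_scope == "sample" && "sample_id" %in% names(cells)) {
    stats::ave(cells$area_um2, cells$sample_id, FUN = mean)
  } else {
    rep(mean(cells$area_um2), n)
  }
  low <- totals < min_counts
  big <- cells$area_um2 > area_fold * mean_area
  keep <- !low & !big
  if (!any(keep)) abort("no cells remain after QC (empty after QC)")
  report <- tibble(
    n_input = n,
    n_low_counts = sum(low),
    n_large_area = sum(big),
    n_retained = sum(keep)
  )
  list(
    cells = cells[keep, , drop = FALSE],
    counts = subset_cells(counts, cells$cell_id[keep]),
    report = report
  )
}

#' Total-count normalization with square-root transform
#'
#' Scales each cell to a common total and square-root transforms:
#' `normalized[g, c] = sqrt(raw[g, c] / total(c) * s)`. Consequently the
#' per-cell sum of squared normalized values equals `s` exactly. The scale
#' factor `s` defaults to the median cell total of the input matrix and is
#' recorded in the returned object.
#'
#' @param counts A [count_matrix()]; every cell must have total counts > 0.
#' @param scale_factor A positive number, or `"median"` (the default) for
#'   the median per-cell total.
#' @return The [count_matrix()] with the `normalized` layer and
#'   `scale_factor` filled in.
#' @export
normalize_counts <- function(counts, scale_factor = "median") {
  totals <- Matrix::colSums(counts$raw)
  if (any(totals == 0)) {
    bad <- cells_of(counts)[totals == 0]
    abort(paste0("cells with zero total counts cannot be normalized: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..."))
  }
  s <- if (identical(scale_factor, "median")) median(totals) else scale_factor
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    abort("scale_factor must be a positive number or \"median\"")
  }
  norm <- counts$raw
  # column-scale then sqrt; dgCMatrix @x runs column-wise
  norm@x <- sqrt(norm@x / rep.int(totals, diff(norm@p)) * s)
  count_matrix(counts$raw, normalized = norm, scale_factor = s)
}
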
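# Internal helpers shared across modules.

#' Construct a count matrix container
#'
#' Bundles a genes-by-cells sparse count matrix with an optional normalized
#' layer and the scale factor recorded at normalization time. Rows are genes,
#' columns are cells; dimnames are mandatory because every downstream join is
#' by `cell_id` and gene name.
#'
#' @param raw A genes-by-cells matrix of non-negative integer counts
#'   (base matrix or any Matrix class; coerced to `dgCMatrix`).
#' @param normalized Optional normalized layer of identical shape.
#' @param scale_factor Positive scale factor used to produce `normalized`,
#'   or `NULL` when no normalized layer is present.
#' @return An object of class `count_matrix`: a list with elements `raw`,
#'   `normalized` and `scale_factor`.
#' @export
count_matrix <- function(raw, normalized = NULL, scale_factor = NULL) {
  raw <- methods::as(methods::as(methods::as(raw, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if ((nrow(raw) > 0L && is.null(rownames(raw))) ||
      (ncol(raw) > 0L && is.null(colnames(raw)))) {
    abort("count matrix must carry gene rownames and cell colnames")
  }
  if (is.null(rownames(raw))) rownames(raw) <- character(0)
  if (is.null(colnames(raw))) colnames(raw) <- character(0)
  if (any(raw@x < 0)) abort("raw counts must be non-negative")
  if (anyDuplicated(colnames(raw))) abort("cell ids in counts must be unique")
  if (!is.null(normalized)) {
    normalized <- methods::as(methods::as(methods::as(normalized, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    stopifnot(identical(dim(normalized), dim(raw)))
    dimnames(normalized) <- dimnames(raw)
  }
  structure(
    list(raw = raw, normalized = normalized, scale_factor = scale_factor),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d cells; normalized: %s\n",
    nrow(x$raw), ncol(x$raw),
    if (is.null(x$normalized)) "absent"
    else sprintf("present (scale factor %.4g)", x$scale_factor)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$raw)

# Matrix stores zero-extent dimnames as NULL; normalize to character(0)
genes_of <- function(counts) rownames(counts$raw) %||% character(0)
cells_of <- function(counts) colnames(counts$raw) %||% character(0)

# Subset a count_matrix by cell ids (keeps layers aligned).
subset_cells <- function(counts, cell_ids) {
  keep <- match(cell_ids, cells_of(counts))
  if (anyNA(keep)) abort("unknown cell ids in subset")
  count_matrix(
    raw = counts$raw[, keep, drop = FALSE],
    normalized = if (!is.null(counts$normalized)) counts$normalized[, keep, drop = FALSE],
    scale_factor = counts$scale_factor
  )
}

need_normalized <- function(counts, caller) {
  if (is.null(counts$normalized)) {
    abort(sprintf("%s requires a normalized layer; run normalize_counts() first", caller))
  }
  invisible(counts)
}

check_cells_aligned <- function(cells, counts) {
  if (!identical(cells$cell_id, cells_of(counts))) {
    missing_meta <- setdiff(cells_of(counts), cells$cell_id)
    missing_counts <- setdiff(cells$cell_id, cells_of(counts))
    if (length(missing_meta) || length(missing_counts)) {
      abort(paste0(
        "cell metadata and count matrix are misaligned; ",
        if (length(missing_counts)) paste0(
          "cells only in metadata: ",
          paste(head(missing_counts, 5), collapse = ", "),
          if (length(missing_counts) > 5) ", ...", ". "
        ) else "",
        if (length(missing_meta)) paste0(
          "cells only in counts: ",
          paste(head(missing_meta, 5), collapse = ", "),
          if (length(missing_meta) > 5) ", ...", "."
        ) else ""
      ))
    }
    abort("cell metadata and count matrix list the same cells in different order")
  }
  invisible(TRUE)
}

# Pairwise Euclidean distances between two coordinate matrices, computed in
# blocks so n ~ 10^4 stays within memory. Two-dimensional (spatial)
# coordinates use exact coordinate differences — the Gram-matrix identity
# suffers catastrophic cancellation near zero, and spatial results must
# match brute-force scans exactly; higher-dimensional embeddings use the
# matrix-product form for speed.
dist_block <- function(a, b) {
  if (ncol(a) == 2L) {
    d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
    return(sqrt(d2))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% Matrix::t(b)
  d2[d2 < 0] <- 0
  sqrt(as.matrix(d2))
}

# Distance from each row of `query` (n x 2) to its nearest row of `target`,
# blocked over query rows.
nearest_distance <- function(query, target, block = 512L) {
  n <- nrow(query)
  if (nrow(target) == 0L) return(rep(Inf, n))
  out <- numeric(n)
  for (i0 in seq(1L, n, by = block)) {
    idx <- i0:min(i0 + block - 1L, n)
    out[idx] <- apply(dist_block(query[idx, , drop = FALSE], target), 1L, min)
  }
  out
}

# Spearman correlation that tolerates constant vectors (returns NA there;
# callers decide how to flag).
spearman_safe <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

# Distance from a cell to the epidermal boundary line y = depth.
epidermis_distance <- function(y_um, epidermis_depth_um) {
  abs(y_um - epidermis_depth_um)
}
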
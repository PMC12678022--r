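# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Adjusted Rand index between two labelings (independent of any package
# clustering code).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# A minimal one-region, one-type configuration.
tiny_config <- function(n_cells = 100, seed = 1, gene_panel = NULL,
                        gradient_genes = NULL, types = "fibroblast") {
  comp <- setNames(rep(1 / length(types), length(types)), types)
  tissue_config(
    width_um = 400, height_um = 500, epidermis_depth_um = 50,
    regions = list(list(name = "dermis", y_min = 50, y_max = 500,
                        composition = comp)),
    gene_panel = gene_panel %||% tibble::tibble(
      gene = c("G1", "G2", "G3"), program = "all", base_mean = c(5, 2, 1)),
    gradient_genes = gradient_genes,
    n_cells = n_cells, seed = seed
  )
}

# Three well-separated expression programs over three cell types; used for
# clustering and annotation recovery tests.
three_type_config <- function(n_cells = 900, seed = 1) {
  types <- c("fibroblast", "keratinocyte", "myeloid")
  panel <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("FIB", 1:5), program = "fibroblast", base_mean = 8),
    tibble::tibble(gene = paste0("KRT", 1:5), program = "keratinocyte", base_mean = 8),
    tibble::tibble(gene = paste0("MYE", 1:5), program = "myeloid", base_mean = 8),
    tibble::tibble(gene = paste0("HK", 1:10), program = "all", base_mean = 3)
  )
  tissue_config(
    width_um = 600, height_um = 600, epidermis_depth_um = 50,
    regions = list(list(
      name = "mix", y_min = 0, y_max = 600,
      composition = c(fibroblast = 0.4, keratinocyte = 0.35, myeloid = 0.25))),
    gene_panel = panel, n_cells = n_cells, seed = seed
  )
}

three_type_markers <- function() {
  list(fibroblast = paste0("FIB", 1:5),
       keratinocyte = paste0("KRT", 1:5),
       myeloid = paste0("MYE", 1:5))
}

# Build a count_matrix directly from a dense matrix (genes x cells).
dense_counts <- function(m, normalized = NULL, scale_factor = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  count_matrix(m, normalized = normalized, scale_factor = scale_factor)
}

# A normalized count_matrix whose normalized layer is set to an arbitrary
# dense matrix (for statistic-level tests where the raw layer is irrelevant).
normalized_fixture <- function(norm) {
  if (is.null(rownames(norm))) rownames(norm) <- paste0("g", seq_len(nrow(norm)))
  if (is.null(colnames(norm))) colnames(norm) <- paste0("c", seq_len(ncol(norm)))
  raw <- matrix(1, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  count_matrix(raw, normalized = norm, scale_factor = 1)
}

# Random scattered cell table for spatial oracles.
random_cells <- function(n, seed, types = c("A", "B", "C"), n_samples = 1) {
  set.seed(seed)
  tibble::tibble(
    cell_id = sprintf("r%04d", seq_len(n)),
    x_um = runif(n, 0, 400),
    y_um = runif(n, 0, 400),
    area_um2 = 100,
    sample_id = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
    condition = "SS",
    cell_type = sample(types, n, replace = TRUE)
  )
}

# O(n^2) double-loop oracle for neighborhood composition.
brute_composition <- function(cells, radius, types) {
  n <- nrow(cells)
  frac <- matrix(0, n, length(types), dimnames = list(cells$cell_id, types))
  nb <- integer(n)
  for (i in seq_len(n)) {
    cnt <- setNames(numeric(length(types)), types)
    for (j in seq_len(n)) {
      if (i == j) next
      if (cells$sample_id[j] != cells$sample_id[i]) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
      if (d <= radius) cnt[cells$cell_type[j]] <- cnt[cells$cell_type[j]] + 1
    }
    nb[i] <- as.integer(sum(cnt))
    if (nb[i] > 0) frac[i, ] <- cnt / nb[i]
  }
  list(frac = frac, neighbor_count = nb)
}

# O(n^2) oracle for nearest-target distance.
brute_nearest <- function(cells, target_type) {
  vapply(seq_len(nrow(cells)), function(i) {
    idx <- which(cells$cell_type == target_type &
                   cells$sample_id == cells$sample_id[i])
    if (length(idx) == 0) return(Inf)
    min(sqrt((cells$x_um[i] - cells$x_um[idx])^2 +
               (cells$y_um[i] - cells$y_um[idx])^2))
  }, numeric(1))
}

# Hand-built neighborhood_profile object (for direct mixture tests).
manual_profiles <- function(frac, x_um = NULL, y_um = NULL) {
  n <- nrow(frac)
  types <- colnames(frac)
  out <- tibble::tibble(
    cell_id = sprintf("m%04d", seq_len(n)),
    sample_id = "s1",
    x_um = x_um %||% runif(n, 0, 1000),
    y_um = y_um %||% runif(n, 0, 1000),
    neighbor_count = 20L
  )
  colnames(frac) <- paste0("frac_", types)
  out <- dplyr::bind_cols(out, tibble::as_tibble(frac))
  structure(out, radius = 50, types = types,
            class = c("neighborhood_profile", class(out)))
}
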
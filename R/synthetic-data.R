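# Seeded synthetic skin-tissue simulator.
#
# The generator emulates the structure a segmented imaging-based spatial
# transcriptomics run of lesional skin presents to the analysis pipeline:
# a layered rectangle of tissue (epidermal band on top, dermis below), a
# handful of cell types arranged in horizontal composition bands (the
# planted "niches"), negative-binomial expression programs per type, and
# chemokine-like genes whose mean is log-linearly coupled to the distance
# from an anchor (the nearest neutrophil, or the epidermal boundary).

#' Build a synthetic-tissue configuration
#'
#' @param width_um,height_um Tissue rectangle dimensions in micrometres.
#'   The y axis follows the image convention: origin at the top, y
#'   increasing downward, so the epidermis is the band `y < epidermis_depth_um`.
#' @param epidermis_depth_um Thickness of the epidermal band (micrometres).
#' @param regions List of region definitions, each a list with `name`,
#'   `y_min`, `y_max` (micrometres) and `composition`, a named vector of
#'   cell-type proportions summing to 1. Regions must tile `[0, height_um]`
#'   without overlap; cells are scattered uniformly, with expected counts
#'   proportional to region area.
#' @param gene_panel Tibble with columns `gene`, `program` (a cell type, or
#'   `"all"` for housekeeping genes expressed everywhere) and `base_mean`
#'   (negative-binomial mean in cells of the program type, at anchor
#'   distance zero for gradient genes).
#' @param gradient_genes Tibble with columns `gene`, `anchor` (one of
#'   `"nearest_neutrophil"`, `"epidermis_boundary"`), `direction`
#'   (`"increasing"` or `"decreasing"`) and `effect_size`. The gene's mean is
#'   multiplied by `exp(sign * effect_size * d / height_um)` where `d` is the
#'   cell's anchor distance (capped at `height_um`).
#' @param n_cells Number of cells to simulate.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param off_mean Mean count for a gene in cells outside its program.
#' @param area_mean_um2,area_cv Mean and coefficient of variation of the
#'   log-normal cell-area distribution.
#' @param neutrophil_type Name of the cell type used as the
#'   `nearest_neutrophil` anchor.
#' @param condition Condition label attached to the sample (e.g. `"SS"`,
#'   `"HC"`).
#' @param sample_id Sample identifier used to prefix cell ids.
#' @param seed Integer seed; [generate_tissue()] is deterministic given the
#'   configuration (including this seed).
#' @return A validated list of class `tissue_config`.
#' @seealso [default_tissue_config()] for the stock lesional/healthy layouts.
#' @export
tissue_config <- function(width_um, height_um, epidermis_depth_um,
                          regions, gene_panel, gradient_genes = NULL,
                          n_cells = 5000L, dispersion = 2,
                          off_mean = 0.1,
                          area_mean_um2 = 100, area_cv = 0.5,
                          neutrophil_type = "neutrophil",
                          condition = "SS", sample_id = "S1",
                          seed = 1L) {
  cfg <- structure(
    list(
      width_um = width_um, height_um = height_um,
      epidermis_depth_um = epidermis_depth_um,
      regions = regions, gene_panel = as_tibble(gene_panel),
      gradient_genes = if (is.null(gradient_genes)) {
        tibble(gene = character(), anchor = character(),
               direction = character(), effect_size = numeric())
      } else as_tibble(gradient_genes),
      n_cells = as.integer(n_cells), dispersion = dispersion,
      off_mean = off_mean,
      area_mean_um2 = area_mean_um2, area_cv = area_cv,
      neutrophil_type = neutrophil_type,
      condition = condition, sample_id = sample_id,
      seed = as.integer(seed)
    ),
    class = "tissue_config"
  )
  validate_tissue_config(cfg)
}

validate_tissue_config <- function(cfg) {
  with(cfg, {
    if (!(width_um > 0 && height_um > 0 && epidermis_depth_um > 0)) {
      abort("tissue dimensions must be positive")
    }
    if (n_cells <= 0L) abort("n_cells must be positive")
    if (dispersion <= 0) abort("dispersion must be positive")
    if (nrow(gene_panel) == 0L) abort("gene_panel must contain at least one gene")
    if (anyDuplicated(gene_panel$gene)) abort("gene_panel gene names must be unique")
    if (length(regions) == 0L) abort("at least one region is required")
  })
  # regions must not overlap: cells are assigned by band, so an overlap makes
  # the true region label ambiguous.
  bands <- do.call(rbind, lapply(cfg$regions, function(r) {
    if (is.null(r$name) || is.null(r$y_min) || is.null(r$y_max) || is.null(r$composition)) {
      abort("each region needs name, y_min, y_max and composition")
    }
    if (r$y_max <= r$y_min) abort(sprintf("region '%s' has non-positive height", r$name))
    comp <- r$composition
    if (any(comp < 0) || abs(sum(comp) - 1) > 1e-8) {
      abort(sprintf("region '%s' composition must be proportions summing to 1", r$name))
    }
    c(r$y_min, r$y_max)
  }))
  ord <- order(bands[, 1])
  bands <- bands[ord, , drop = FALSE]
  if (nrow(bands) > 1 && any(bands[-1, 1] < bands[-nrow(bands), 2] - 1e-9)) {
    abort("region bands overlap; cells would be unassignable to a unique region")
  }
  bad <- cfg$gradient_genes$gene[!cfg$gradient_genes$gene %in% cfg$gene_panel$gene]
  if (length(bad)) abort(paste0("gradient genes absent from gene_panel: ",
                                paste(bad, collapse = ", ")))
  if (!all(cfg$gradient_genes$anchor %in% c("nearest_neutrophil", "epidermis_boundary"))) {
    abort("gradient anchor must be 'nearest_neutrophil' or 'epidermis_boundary'")
  }
  if (!all(cfg$gradient_genes$direction %in% c("increasing", "decreasing"))) {
    abort("gradient direction must be 'increasing' or 'decreasing'")
  }
  if (!all(is.finite(cfg$gradient_genes$effect_size))) {
    abort("gradient effect sizes must be finite")
  }
  cfg
}

#' Cell types used by the stock skin templates
#' @return Character vector of the seven cell-type labels.
#' @export
skin_cell_types <- function() {
  c("keratinocyte", "fibroblast", "neutrophil", "myeloid",
    "lymphoid", "endothelial", "mural")
}

#' Default gene panel for the skin templates
#'
#' Five marker genes per cell type (named `<TYPE><i>`), twenty housekeeping
#' genes expressed in every cell, and two fibroblast chemokine analogs:
#' `CXCL1L` (a CXCR2-ligand analog, elevated in fibroblasts near neutrophil
#' infiltrates when configured with a decreasing neutrophil-distance
#' gradient) and `CXCL12L` (a CXCR4-ligand analog, elevated distally).
#'
#' @param marker_mean,housekeeping_mean,chemokine_mean Negative-binomial
#'   base means for the three gene classes.
#' @return Tibble with columns `gene`, `program`, `base_mean`.
#' @export
default_gene_panel <- function(marker_mean = 8, housekeeping_mean = 2.5,
                               chemokine_mean = 5) {
  types <- skin_cell_types()
  stubs <- c(keratinocyte = "KRT", fibroblast = "FIB", neutrophil = "NEU",
             myeloid = "MYE", lymphoid = "LYM", endothelial = "END",
             mural = "MUR")
  markers <- purrr::map_dfr(types, function(ty) {
    tibble(gene = sprintf("%s%d", stubs[[ty]], 1:5),
           program = ty, base_mean = marker_mean)
  })
  housekeeping <- tibble(gene = sprintf("HK%02d", 1:20),
                         program = "all", base_mean = housekeeping_mean)
  chemokines <- tibble(gene = c("CXCL1L", "CXCL12L"),
                       program = "fibroblast", base_mean = chemokine_mean)
  dplyr::bind_rows(markers, housekeeping, chemokines)
}

#' Stock tissue configurations
#'
#' The `"SS"` template lays out a lesional skin biopsy: an epidermal band on
#' top of six dermal composition bands (seven regions in all), with a dense
#' neutrophil aggregate in the mid-to-upper dermis, and the two fibroblast
#' chemokine analogs coupled to neutrophil distance (`CXCL1L` decreasing,
#' i.e. highest in neutrophil-proximal fibroblasts; `CXCL12L` increasing).
#' The `"HC"` template has the same geometry but no neutrophil aggregate and
#' no expression gradients.
#'
#' @param condition `"SS"` (lesional) or `"HC"` (healthy control).
#' @param n_cells Number of cells (default 5000).
#' @param seed Integer seed.
#' @param effect_size Gradient effect size for the chemokine analogs
#'   (log-scale slope over one tissue height).
#' @param sample_id Sample identifier.
#' @return A `tissue_config`.
#' @export
default_tissue_config <- function(condition = c("SS", "HC"), n_cells = 5000L,
                                  seed = 1L, effect_size = 2,
                                  sample_id = NULL) {
  condition <- match.arg(condition)
  comp <- function(...) {
    v <- c(...)
    v / sum(v)
  }
  aggregate_comp <- if (condition == "SS") {
    comp(neutrophil = 0.50, fibroblast = 0.25, myeloid = 0.13,
         lymphoid = 0.12)
  } else {
    comp(fibroblast = 0.50, myeloid = 0.20, lymphoid = 0.15,
         endothelial = 0.15)
  }
  # Composition bands are separated by thin hypocellular seams (60 um, just
  # over the 50-um niche radius) standing in for the basement membrane and
  # the paucicellular collagen planes between dermal layers. Fibroblasts are
  # concentrated in two niches, mirroring the lesional architecture the
  # template emulates: an upper dermal niche shared with the neutrophil
  # aggregate, and a fibroblast-rich deep dermal niche far from it; the
  # intervening bands are immune- and vessel-dominated.
  seam <- 60
  band <- 200
  y0 <- c(0, 100 + seam + (band + seam) * 0:5)
  y1 <- c(100, y0[-1] + band)
  regions <- list(
    list(name = "epidermis", y_min = y0[1], y_max = y1[1],
         composition = comp(keratinocyte = 0.88, lymphoid = 0.06,
                            myeloid = 0.06)),
    list(name = "papillary_dermis", y_min = y0[2], y_max = y1[2],
         composition = comp(keratinocyte = 0.22, endothelial = 0.30,
                            myeloid = 0.19, lymphoid = 0.19, mural = 0.10)),
    list(name = "infiltrate", y_min = y0[3], y_max = y1[3],
         composition = aggregate_comp),
    list(name = "upper_reticular", y_min = y0[4], y_max = y1[4],
         composition = comp(myeloid = 0.40, lymphoid = 0.33,
                            endothelial = 0.17, mural = 0.10)),
    list(name = "mid_reticular", y_min = y0[5], y_max = y1[5],
         composition = comp(endothelial = 0.50, lymphoid = 0.20,
                            myeloid = 0.20, mural = 0.10)),
    list(name = "lower_reticular", y_min = y0[6], y_max = y1[6],
         composition = comp(mural = 0.50, endothelial = 0.35,
                            lymphoid = 0.08, myeloid = 0.07)),
    list(name = "deep_dermis", y_min = y0[7], y_max = y1[7],
         composition = comp(fibroblast = 0.70, endothelial = 0.12,
                            mural = 0.08, lymphoid = 0.05, myeloid = 0.05))
  )
  gradients <- if (condition == "SS") {
    tibble(
      gene = c("CXCL1L", "CXCL12L"),
      anchor = "nearest_neutrophil",
      direction = c("decreasing", "increasing"),
      effect_size = effect_size
    )
  } else NULL
  tissue_config(
    width_um = 500, height_um = 1660, epidermis_depth_um = 100,
    regions = regions, gene_panel = default_gene_panel(),
    gradient_genes = gradients, n_cells = n_cells,
    condition = condition,
    sample_id = sample_id %||% paste0(condition, "1"),
    seed = seed
  )
}

#' Simulate a tissue from a configuration
#'
#' Scatters cells uniformly within their composition bands (expected counts
#' proportional to band area), draws cell types from each band's
#' composition, draws log-normal cell areas, computes anchor distances
#' (nearest neutrophil; epidermal boundary line `y = epidermis_depth_um`),
#' and samples counts per gene from negative-binomial programs whose means
#' are modulated multiplicatively by `exp(+/- effect_size * d / height_um)`
#' for configured gradient genes. Deterministic given the configuration seed.
#'
#' @param config A [tissue_config()].
#' @param seed Optional override of `config$seed`.
#' @return An object of class `synthetic_tissue`: a list with
#'   * `cells`: tibble `cell_id, x_um, y_um, area_um2, sample_id, condition`;
#'   * `counts`: a [count_matrix()] with the raw layer filled;
#'   * `truth`: tibble with the generating `true_type`, `true_region`, and
#'     the anchor distances `neutrophil_distance_um`, `boundary_distance_um`;
#'   * `config`: the configuration used.
#' @export
generate_tissue <- function(config, seed = NULL) {
  stopifnot(inherits(config, "tissue_config"))
  config <- validate_tissue_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)

  regions <- config$regions
  areas <- vapply(regions, function(r) (r$y_max - r$y_min) * config$width_um,
                  numeric(1))
  n_region <- as.vector(rmultinom(1, config$n_cells, areas / sum(areas)))

  cells_list <- purrr::map2(regions, n_region, function(r, n) {
    if (n == 0L) return(NULL)
    tibble(
      x_um = runif(n, 0, config$width_um),
      y_um = runif(n, r$y_min, r$y_max),
      true_region = r$name,
      true_type = sample(names(r$composition), n, replace = TRUE,
                         prob = r$composition)
    )
  })
  cells <- dplyr::bind_rows(cells_list)
  n <- nrow(cells)
  cells$cell_id <- sprintf("%s_c%05d", config$sample_id, seq_len(n))

  sdlog <- sqrt(log(1 + config$area_cv^2))
  meanlog <- log(config$area_mean_um2) - sdlog^2 / 2
  cells$area_um2 <- rlnorm(n, meanlog, sdlog)

  xy <- cbind(cells$x_um, cells$y_um)
  neut <- xy[cells$true_type == config$neutrophil_type, , drop = FALSE]
  neut_d <- nearest_distance(xy, neut)
  bound_d <- epidermis_distance(cells$y_um, config$epidermis_depth_um)

  panel <- config$gene_panel
  mu <- matrix(config$off_mean, nrow = nrow(panel), ncol = n,
               dimnames = list(panel$gene, cells$cell_id))
  for (g in seq_len(nrow(panel))) {
    if (panel$program[g] == "all") {
      mu[g, ] <- panel$base_mean[g]
    } else {
      mu[g, cells$true_type == panel$program[g]] <- panel$base_mean[g]
    }
  }
  if (nrow(config$gradient_genes)) {
    d_scale <- config$height_um
    for (k in seq_len(nrow(config$gradient_genes))) {
      gg <- config$gradient_genes[k, ]
      d <- switch(gg$anchor,
                  nearest_neutrophil = neut_d,
                  epidermis_boundary = bound_d)
      d <- pmin(d, d_scale)  # also tames samples with no anchor cells
      s <- if (gg$direction == "increasing") 1 else -1
      mu[gg$gene, ] <- mu[gg$gene, ] * exp(s * gg$effect_size * d / d_scale)
    }
  }

  raw <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                        size = config$dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
  counts <- count_matrix(Matrix::Matrix(raw, sparse = TRUE))

  structure(
    list(
      cells = tibble(
        cell_id = cells$cell_id, x_um = cells$x_um, y_um = cells$y_um,
        area_um2 = cells$area_um2,
        sample_id = config$sample_id, condition = config$condition
      ),
      counts = counts,
      truth = tibble(
        cell_id = cells$cell_id,
        true_type = cells$true_type,
        true_region = cells$true_region,
        neutrophil_distance_um = neut_d,
        boundary_distance_um = bound_d
      ),
      config = config
    ),
    class = "synthetic_tissue"
  )
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> %d cells, %d genes, sample %s (%s), %d regions\n",
    nrow(x$cells), nrow(x$counts$raw), x$config$sample_id,
    x$config$condition, length(x$config$regions)
  ))
  invisible(x)
}

#' Combine tissues from several samples into one dataset
#'
#' @param ... `synthetic_tissue` objects sharing the same gene panel.
#' @return A list with `cells`, `counts`, `truth` spanning all samples.
#' @export
combine_tissues <- function(...) {
  tissues <- list(...)
  stopifnot(length(tissues) >= 1)
  genes <- genes_of(tissues[[1]]$counts)
  for (tt in tissues) {
    if (!identical(genes_of(tt$counts), genes)) {
      abort("tissues must share an identical gene panel to be combined")
    }
  }
  list(
    cells = dplyr::bind_rows(lapply(tissues, `[[`, "cells")),
    counts = count_matrix(do.call(cbind, lapply(tissues, function(tt) tt$counts$raw))),
    truth = dplyr::bind_rows(lapply(tissues, `[[`, "truth"))
  )
}

#' Write a tissue to disk as a plain-text fixture
#'
#' Emits `counts.mtx` (MatrixMarket, genes x cells), `genes.txt` (one gene
#' per line), `cells.tsv` (cell metadata) and `truth.tsv` into `directory`.
#' The file set round-trips losslessly through [read_dataset()].
#'
#' @param tissue A `synthetic_tissue` (or any list with `cells`, `counts`,
#'   optionally `truth`).
#' @param directory Output directory, created if needed.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_fixture <- function(tissue, directory) {
  if (nrow(tissue$counts$raw) == 0L) abort("refusing to write a fixture with an empty gene list")
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, mode = 2L) != 0L) {
    abort(sprintf("cannot write to directory '%s'", directory))
  }
  paths <- c(
    counts = file.path(directory, "counts.mtx"),
    genes = file.path(directory, "genes.txt"),
    cells = file.path(directory, "cells.tsv"),
    truth = file.path(directory, "truth.tsv")
  )
  Matrix::writeMM(tissue$counts$raw, paths[["counts"]])
  writeLines(genes_of(tissue$counts), paths[["genes"]])
  write.table(tissue$cells, paths[["cells"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(tissue$truth)) {
    write.table(tissue$truth, paths[["truth"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
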
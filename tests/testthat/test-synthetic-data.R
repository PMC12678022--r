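test_that("degenerate single-region, single-type tissue is uniform", {
  tis <- generate_tissue(tiny_config(n_cells = 100, seed = 3))
  expect_equal(nrow(tis$cells), 100)
  expect_setequal(unique(tis$truth$true_type), "fibroblast")
  expect_setequal(unique(tis$truth$true_region), "dermis")
  expect_true(all(tis$cells$x_um >= 0 & tis$cells$x_um <= 400))
  expect_true(all(tis$cells$y_um >= 50 & tis$cells$y_um <= 500))
  expect_true(all(tis$cells$area_um2 > 0))
})

test_that("generation is deterministic given config and seed", {
  cfg <- default_tissue_config("SS", n_cells = 400, seed = 11)
  a <- generate_tissue(cfg)
  b <- generate_tissue(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  expect_identical(as.matrix(a$counts$raw), as.matrix(b$counts$raw))
  d <- generate_tissue(cfg, seed = 12)
  expect_false(identical(a$cells$x_um, d$cells$x_um))
})

test_that("planted neutrophil-distance gradient has the configured sign", {
  # gradient gene expressed in all cells so the correlation is not
  # confounded by cell-type programs
  panel <- tibble::tibble(
    gene = c("GRAD", "HK1", "HK2"), program = "all", base_mean = c(6, 3, 3))
  # neutrophils confined to a top band so anchor distances span a large
  # fraction of the tissue height
  cfg <- tissue_config(
    width_um = 800, height_um = 800, epidermis_depth_um = 50,
    regions = list(
      list(name = "aggregate", y_min = 0, y_max = 100,
           composition = c(neutrophil = 0.9, fibroblast = 0.1)),
      list(name = "dermis", y_min = 100, y_max = 800,
           composition = c(fibroblast = 1))),
    gene_panel = panel,
    gradient_genes = tibble::tibble(
      gene = "GRAD", anchor = "nearest_neutrophil",
      direction = "decreasing", effect_size = 2),
    n_cells = 2000, seed = 5
  )
  tis <- generate_tissue(cfg)

  # independent O(n^2) recomputation of anchor distances
  cells <- dplyr::mutate(tis$cells, cell_type = tis$truth$true_type)
  d_oracle <- brute_nearest(cells, "neutrophil")
  expect_equal(tis$truth$neutrophil_distance_um, d_oracle, tolerance = 1e-12)

  rho <- cor(as.numeric(tis$counts$raw["GRAD", ]), d_oracle,
             method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("region compositions are recovered within multinomial error", {
  cfg <- default_tissue_config("SS", n_cells = 6000, seed = 21)
  tis <- generate_tissue(cfg)
  for (r in cfg$regions) {
    in_region <- tis$truth$true_region == r$name
    emp <- table(factor(tis$truth$true_type[in_region],
                        levels = skin_cell_types())) / sum(in_region)
    conf <- setNames(rep(0, length(skin_cell_types())), skin_cell_types())
    conf[names(r$composition)] <- r$composition
    expect_lt(max(abs(emp - conf)), 0.05)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(tissue_config(
    width_um = 100, height_um = 100, epidermis_depth_um = 10,
    regions = list(
      list(name = "a", y_min = 0, y_max = 60, composition = c(A = 1)),
      list(name = "b", y_min = 50, y_max = 100, composition = c(A = 1))),
    gene_panel = tibble::tibble(gene = "G1", program = "all", base_mean = 1)
  ), "overlap")
  expect_error(tissue_config(
    width_um = 100, height_um = 100, epidermis_depth_um = 10,
    regions = list(list(name = "a", y_min = 0, y_max = 100,
                        composition = c(A = 0.5, B = 0.2))),
    gene_panel = tibble::tibble(gene = "G1", program = "all", base_mean = 1)
  ), "summing to 1")
  expect_error(tissue_config(
    width_um = 100, height_um = 100, epidermis_depth_um = 10,
    regions = list(list(name = "a", y_min = 0, y_max = 100,
                        composition = c(A = 1))),
    gene_panel = tibble::tibble(gene = character(), program = character(),
                                base_mean = numeric())
  ), "at least one gene")
  cfg <- tiny_config()
  expect_error(
    generate_tissue(structure(c(unclass(cfg), list(bogus = 1)),
                              class = "tissue_config")),
    NA)  # extra fields are ignored, not fatal
})

test_that("fixture files round-trip losslessly through the reader", {
  tis <- generate_tissue(default_tissue_config("SS", n_cells = 2000, seed = 7))
  dir <- withr::local_tempdir()
  paths <- write_fixture(tis, dir)
  back <- read_dataset(paths[["counts"]], paths[["genes"]], paths[["cells"]])
  expect_identical(back$cells$cell_id, tis$cells$cell_id)
  expect_equal(back$cells$x_um, tis$cells$x_um, tolerance = 1e-12)
  expect_equal(back$cells$y_um, tis$cells$y_um, tolerance = 1e-12)
  expect_identical(rownames(back$counts$raw), rownames(tis$counts$raw))
  expect_equal(as.matrix(back$counts$raw), as.matrix(tis$counts$raw),
               ignore_attr = TRUE)
})

test_that("small fixture round-trip is exact and errors are informative", {
  tis <- generate_tissue(tiny_config(n_cells = 10, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_fixture(tis, dir)
  back <- read_dataset(paths[["counts"]], paths[["genes"]], paths[["cells"]])
  expect_equal(as.matrix(back$counts$raw), as.matrix(tis$counts$raw),
               ignore_attr = TRUE)

  # MatrixMarket stores no cell names, so an extra metadata row surfaces as
  # a size mismatch naming both counts
  meta <- utils::read.delim(paths[["cells"]])
  meta <- rbind(meta, meta[1, ])
  meta$cell_id[nrow(meta)] <- "ghost_cell"
  extra <- file.path(dir, "cells_extra.tsv")
  write.table(meta, extra, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(paths[["counts"]], paths[["genes"]], extra),
               "11 cells.*10 columns")

  # malformed MatrixMarket header
  bad <- file.path(dir, "bad.mtx")
  writeLines(c("%% not matrixmarket", "1 1 1"), bad)
  expect_error(read_dataset(bad, paths[["genes"]], paths[["cells"]]),
               "MatrixMarket")
})

test_that("dense delimited counts are read exactly", {
  dir <- withr::local_tempdir()
  cmat <- file.path(dir, "counts.csv")
  writeLines(c("gene,cA,cB", "g1,1,4", "g2,0,2", "g3,5,3"), cmat)
  meta <- file.path(dir, "cells.csv")
  writeLines(c("cell_id,x_um,y_um", "cA,0,0", "cB,1,1"), meta)
  dat <- read_dataset(cmat, metadata = meta)
  expect_equal(unname(as.matrix(dat$counts$raw)),
               matrix(c(1, 0, 5, 4, 2, 3), nrow = 3))
  expect_identical(rownames(dat$counts$raw), c("g1", "g2", "g3"))
  expect_identical(colnames(dat$counts$raw), c("cA", "cB"))

  # named columns let an alignment error name the offending cell
  meta2 <- file.path(dir, "cells2.csv")
  writeLines(c("cell_id,x_um,y_um", "cA,0,0", "cB,1,1", "ghost_cell,2,2"),
             meta2)
  expect_error(read_dataset(cmat, metadata = meta2), "ghost_cell")
})

test_that("a fixture with no genes is refused", {
  tis <- generate_tissue(tiny_config(n_cells = 5, seed = 1))
  tis$counts <- count_matrix(tis$counts$raw[character(0), , drop = FALSE])
  expect_error(write_fixture(tis, withr::local_tempdir()), "empty gene list")
})

test_that("combined tissues keep samples distinct", {
  a <- generate_tissue(default_tissue_config("SS", n_cells = 300, seed = 1))
  b <- generate_tissue(default_tissue_config("HC", n_cells = 300, seed = 2))
  both <- combine_tissues(a, b)
  expect_equal(nrow(both$cells), 600)
  expect_setequal(unique(both$cells$condition), c("SS", "HC"))
  expect_equal(ncol(both$counts$raw), 600)
})
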
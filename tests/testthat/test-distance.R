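test_that("distance to nearest target matches hand geometry", {
  cells <- tibble::tibble(
    cell_id = c("t", "q"),
    x_um = c(0, 3), y_um = c(0, 4),
    sample_id = "s1",
    cell_type = c("neutrophil", "fibroblast")
  )
  dmap <- distance_to_nearest(cells, "neutrophil")
  expect_equal(dmap$distance_um[dmap$cell_id == "q"], 5)
  expect_equal(dmap$distance_um[dmap$cell_id == "t"], 0)
  expect_true(all(dmap$defined))
})

test_that("samples without target cells are flagged undefined", {
  cells <- tibble::tibble(
    cell_id = c("a", "b", "c"),
    x_um = c(0, 1, 2), y_um = 0,
    sample_id = c("s1", "s1", "s2"),
    cell_type = c("neutrophil", "fibroblast", "fibroblast")
  )
  dmap <- distance_to_nearest(cells, "neutrophil")
  expect_false(dmap$defined[dmap$cell_id == "c"])
  expect_equal(dmap$distance_um[dmap$cell_id == "c"], Inf)
  expect_true(dmap$defined[dmap$cell_id == "b"])
  expect_error(distance_to_nearest(cells, "astrocyte"), "astrocyte")
})

test_that("nearest distances equal the brute-force scan", {
  for (seed in 1:5) {
    cells <- random_cells(500, seed = seed, n_samples = 2)
    dmap <- distance_to_nearest(cells, "A")
    expect_equal(dmap$distance_um, brute_nearest(cells, "A"),
                 tolerance = 1e-9)
  }
})

test_that("distance bins validate and provide both printed presets", {
  b <- distance_bins()
  expect_equal(b$proximal_max, 30)
  expect_equal(b$distal_min, 300)
  n <- distance_bins("narrow")
  expect_equal(n$proximal_max, 10)
  expect_equal(n$distal_min, 50)
  custom <- distance_bins(proximal_max = 20, distal_min = 100)
  expect_equal(custom$proximal_max, 20)
  expect_error(distance_bins(proximal_max = 400), "proximal_max")
})

test_that("proximal/distal DE picks the right cells and direction", {
  set.seed(20)
  n <- 120
  # fibroblasts at known distances from a neutrophil wall at x = 0
  cells <- tibble::tibble(
    cell_id = sprintf("f%03d", 1:n),
    x_um = rep(c(5, 150, 400), each = n / 3),  # proximal, middle, distal
    y_um = runif(n, 0, 1000),
    sample_id = "s1",
    cell_type = "fibroblast"
  )
  wall <- tibble::tibble(
    cell_id = sprintf("n%03d", 1:30),
    x_um = 0, y_um = seq(0, 1000, length.out = 30),
    sample_id = "s1", cell_type = "neutrophil"
  )
  cells <- dplyr::bind_rows(cells, wall)
  prox_gene <- ifelse(cells$x_um < 100, 8, 2) + rpois(nrow(cells), 1)
  flat_gene <- rpois(nrow(cells), 4)
  norm <- rbind(PROX = prox_gene, FLAT = flat_gene)
  colnames(norm) <- cells$cell_id
  counts <- normalized_fixture(norm)

  dmap <- distance_to_nearest(cells, "neutrophil")
  out <- proximal_distal_de(counts, cells, dmap, "fibroblast",
                            bins = distance_bins())
  expect_true(out$significant[out$gene == "PROX"])
  expect_gt(out$log2_fc[out$gene == "PROX"], 0)
  expect_false(isTRUE(out$significant[out$gene == "FLAT"]))

  # middle cells are excluded: bins tight enough that no proximal cells
  # remain gives a binning error reporting occupancy
  expect_error(
    proximal_distal_de(counts, cells, dmap, "fibroblast",
                       bins = distance_bins(proximal_max = 1,
                                            distal_min = 300)),
    "0 proximal")
})

test_that("distance correlation ranks monotone and constant genes correctly", {
  set.seed(21)
  n <- 60
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:n),
    x_um = runif(n, 10, 400), y_um = 0,
    sample_id = "s1", cell_type = "fibroblast"
  )
  target <- tibble::tibble(cell_id = "t", x_um = 0, y_um = 0,
                           sample_id = "s1", cell_type = "neutrophil")
  all_cells <- dplyr::bind_rows(cells, target)
  dmap <- distance_to_nearest(all_cells, "neutrophil")
  d <- dmap$distance_um[match(cells$cell_id, dmap$cell_id)]
  norm <- rbind(EQ_DIST = c(d, 0), CONST = rep(2, n + 1),
                ANTI = c(max(d) - d, 0))
  colnames(norm) <- all_cells$cell_id
  counts <- normalized_fixture(norm)
  out <- distance_correlation_rank(counts, all_cells, dmap, "fibroblast")
  expect_equal(out$rho[out$gene == "EQ_DIST"], 1)
  expect_equal(out$rank[out$gene == "EQ_DIST"], nrow(out))
  expect_equal(out$rho[out$gene == "CONST"], 0)
  expect_true(out$constant[out$gene == "CONST"])
  expect_equal(out$rank[out$gene == "ANTI"], 1)
})

test_that("boundary profiles recover planted epidermal gradients", {
  base <- default_gene_panel()
  cfg <- tissue_config(
    width_um = 500, height_um = 1200, epidermis_depth_um = 100,
    regions = list(list(
      name = "dermis", y_min = 100, y_max = 1200,
      composition = c(fibroblast = 1))),
    # housekeeping ballast keeps per-cell totals roughly constant so the
    # total-count normalization does not imprint the gradients onto FLAT
    gene_panel = dplyr::bind_rows(
      tibble::tibble(gene = c("DOWN", "UP", "FLAT"), program = "all",
                     base_mean = c(4, 4, 4)),
      tibble::tibble(gene = sprintf("HK%02d", 1:25), program = "all",
                     base_mean = 4)),
    gradient_genes = tibble::tibble(
      gene = c("DOWN", "UP"),
      anchor = "epidermis_boundary",
      direction = c("decreasing", "increasing"),
      effect_size = 2),
    n_cells = 2000, seed = 8
  )
  tis <- generate_tissue(cfg)
  counts <- normalize_counts(tis$counts)

  down <- boundary_profile(counts, tis$cells, "DOWN", n_bins = 15,
                           epidermis_depth_um = 100)
  up <- boundary_profile(counts, tis$cells, "UP", n_bins = 15,
                         epidermis_depth_um = 100)
  flat <- boundary_profile(counts, tis$cells, "FLAT", n_bins = 15,
                           epidermis_depth_um = 100)
  expect_lt(attr(down, "trend_rho"), -0.2)
  expect_gt(attr(up, "trend_rho"), 0.2)
  expect_lt(abs(attr(flat, "trend_rho")), 0.1)
  expect_equal(nrow(down), 15)
  expect_error(boundary_profile(counts, tis$cells, "NOPE", 10, 100), "NOPE")
})
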
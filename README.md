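# dermalniche

Spatial niche analysis of immune-acting fibroblasts in inflamed skin.

## The problem

Neutrophilic dermatoses (Sweet syndrome, pyoderma gangrenosum) are defined
by a dense dermal neutrophil infiltrate. Single-molecule spatial
transcriptomics of lesional skin can resolve *where* neutrophil-recruiting
cells sit — in particular whether chemokine-expressing fibroblasts form
positionally distinct states: a CXCR2-ligand–expressing subset near the
infiltrate and a CXCL12-expressing subset far from it, each in its own
tissue niche.

`dermalniche` implements the full computational chain needed to ask that
question of a segmented cell-by-gene spatial dataset, plus a seeded
synthetic skin-tissue generator so the whole chain is testable without
patient data:

* **QC and normalization** — remove cells with fewer than 20 counts or
  area over 5× the mean cell area; normalize to total counts per cell with
  a square-root transform.
* **Reduction, clustering, annotation** — PCA (50 components), shared
  nearest-neighbor Leiden clustering (resolution 0.4), marker-dictionary
  annotation.
* **Marker statistics** — two-sided Wilcoxon rank-sum on normalized
  values with a `min.pct = 0.25` detection prefilter, pseudocounted
  `log2((mean_a + 1)/(mean_b + 1))` fold changes, Benjamini–Hochberg
  adjustment (significant: `p_adj < 0.05`, `|log2FC| > 0.2`).
* **Niche analysis** — the core: for each cell, the cell-type composition
  within a 50 µm radius; compositions clustered with a diagonal-covariance
  Gaussian mixture fitted by EM, the number of niches G chosen by BIC
  (`−2 log L + k log n`, selection on a spatially thinned subset of
  profiles) or fixed at 7.
* **Distance analyses** — per-sample distance to the nearest neutrophil;
  proximal (<30 µm) vs distal (>300 µm) fibroblast differential
  expression; gene ranking by Spearman correlation with neutrophil
  distance; expression-vs-epidermis-depth profiles.
* **Signature scores** — gene-set module scores against expression-matched
  binned control genes (25 bins, 100 controls per gene), and marker-mean
  deconvolution-style summaries.
* **Pipeline driver** — `run_pipeline()` executes
  simulate → qc → normalize → annotate → niche → distance → score from one
  (YAML-able) config with a single seed and writes every stage table.

All user-facing functions take plain data frames (a cell table with
`cell_id`, `x_um`, `y_um`, `area_um2`, `sample_id`, `condition`,
`cell_type`) plus a light `count_matrix` container, and return tibbles;
fitted objects support `tidy()`/`glance()` and results have
`autoplot()`/`plot_*()` methods.

## Worked example

```r
library(dermalniche)
library(dplyr)

# a 5000-cell lesional-skin tissue: epidermis, neutrophil aggregate in the
# mid-to-upper dermis, fibroblast-rich deep dermis, chemokine analogs
# coupled to neutrophil distance
tis <- generate_tissue(default_tissue_config("SS", n_cells = 5000, seed = 1))
cells <- mutate(tis$cells, cell_type = tis$truth$true_type)

qc <- qc_filter(cells, tis$counts)
qc$report
#> # A tibble: 1 × 4
#>   n_input n_low_counts n_large_area n_retained
#>     <int>        <int>        <int>      <int>
#> 1    5000            0            1       4999

counts <- normalize_counts(qc$counts)

prof <- neighborhood_composition(qc$cells, radius = 50)
fit <- fit_niches(prof, G = "auto", g_range = 1:12, seed = 1,
                  epidermis_depth_um = 100)
glance(fit)
#> # A tibble: 1 × 4
#>   selected_G     bic  loglik n_models_compared
#>        <int>   <dbl>   <dbl>             <int>
#> 1          7 -14369. 107255.                12
```

BIC over G = 1..12 picks 7 niches — the planted count: the epidermal band,
papillary dermis, the neutrophil infiltrate, three immune/vascular dermal
bands, and the deep fibroblast-rich dermis. Niche labels are ordered by
depth, so niche 1 is the epidermis and niche 7 the deepest.

```r
dmap <- distance_to_nearest(qc$cells, "neutrophil")
de <- proximal_distal_de(counts, qc$cells, dmap, "fibroblast")
filter(de, significant) |> select(gene, log2_fc, p_adj)
#> # A tibble: 2 × 3
#>   gene    log2_fc    p_adj
#>   <chr>     <dbl>    <dbl>
#> 1 CXCL1L    0.616 9.70e-34
#> 2 CXCL12L  -0.537 2.88e-33
```

Fibroblasts within 30 µm of a neutrophil over-express the CXCR2-ligand
analog `CXCL1L` (positive log2FC = proximal-elevated), while fibroblasts
more than 300 µm away over-express the CXCR4-ligand analog `CXCL12L`
(negative log2FC = distal-elevated) —
the two positionally distinct chemokine programs the pipeline is built to
detect, recovered here from the generator's planted gradients
(`effect_size = 2` on the log scale over one tissue height).

`plot_tissue()`, `plot_bic()`, `plot_niche_composition()` and
`autoplot()` on marker tables / boundary profiles give the standard
figures.

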
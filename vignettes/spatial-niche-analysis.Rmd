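---
title: "Spatial niche analysis of immune-acting fibroblasts in inflamed skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial niche analysis of immune-acting fibroblasts in inflamed skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dermalniche)
library(dplyr)
```

# The problem

Neutrophilic dermatoses such as Sweet syndrome are defined by a dense
dermal neutrophil infiltrate. Single-molecule spatial transcriptomics of
lesional skin makes it possible to ask *where* the cells that recruit those
neutrophils sit: are chemokine-expressing fibroblasts scattered uniformly,
or organized into positionally distinct states — one near the infiltrate,
one far from it? Answering that requires a chain of computations:
cell-level quality control, normalization, cell-type annotation,
neighborhood-composition "niche" clustering, and differential expression
conditioned on the distance to the nearest neutrophil.

`dermalniche` implements that chain as composable, data-frame-first
functions, together with a seeded synthetic-tissue generator so every stage
is testable end to end without access to patient data.

# Quality control and normalization

Cells are removed when their total transcript count falls below
`min_counts` (default 20) or their segmented area exceeds `area_fold`
(default 5) times the average cell area. Two details are deliberate:

* the mean area is computed **once**, over all input cells, before any
  removal — the filter is a single pass, never iterated, because an
  iterated filter would depend on removal order and produce different
  retained sets;
* the average is taken per sample by default (`area_scope = "sample"`),
  since segmentation scale varies between slides; a global mean is
  available as an option.

Genes are never filtered at QC.

Normalization scales each cell to a common total `s` and applies a square
root: `normalized[g, c] = sqrt(raw[g, c] / total(c) * s)`. The square-root
transform is a standard variance stabilizer for counts in the tens-per-cell
regime typical of targeted imaging panels. An exact algebraic consequence —
used as a conservation test throughout the suite — is that the per-cell sum
of squared normalized values equals `s`. The scale factor is unspecified in
most descriptions of this normalization; the package defaults to the
median post-QC cell total (keeping normalized magnitudes near raw scale)
and records the value used in the returned object.

# Reduction, clustering, and marker statistics

`reduce_pca()` standardizes each gene of the normalized layer and takes the
top principal components (50 by default, matching common practice for this
data type). `cluster_cells()` builds a k = 20 shared-nearest-neighbor graph
(Euclidean in PC space, Jaccard-style weights pruned below 1/15) and
partitions it with the Leiden algorithm under the modularity objective at
resolution 0.4. Labels are renumbered by decreasing cluster size and the
run is seeded, so results are reproducible; a nonlinear embedding (UMAP) is
deliberately out of scope because every downstream quantity flows from the
PC graph, not from a 2-d picture.

`rank_markers()` is the two-group statistic reused everywhere (cluster
markers, per-niche fibroblast programs, proximal/distal contrasts):

* genes are tested only if detected (normalized value > 0) in at least
  `min_pct` (default 0.25) of **either** group — the convention of the
  widely used single-cell marker tools this mirrors;
* the test is a two-sided Wilcoxon rank-sum on normalized values, computed
  by full enumeration of rank assignments when both groups have at most 8
  cells and by the tie-corrected normal approximation (no continuity
  correction) otherwise;
* the effect size is `log2((mean_a + 1) / (mean_b + 1))` on normalized
  means. The pseudocount of 1 avoids division by zero; base-2 logs are used
  everywhere and stated in the column name;
* Benjamini–Hochberg adjustment runs over the tested genes, and rows are
  flagged significant at `p_adj < 0.05` with `|log2FC|` above a threshold
  (default 0.2, the threshold used for the niche contrasts this package
  reproduces).

`annotate_clusters()` assigns each cluster the label whose marker genes
(user-supplied dictionary) have the highest mean normalized expression over
the cluster, recording margin and runner-up; exact ties break
alphabetically and are flagged, and clusters with no marker signal are
`"unassigned"`.

# The niche model

`neighborhood_composition()` computes, for every cell, the cell-type
composition of its neighborhood: all annotated cells within a closed
Euclidean ball of radius 50 µm (the field's standard niche radius),
excluding the index cell itself (self-inclusion would bias every profile
toward its own type), within the same sample only. Counts are converted to
fractions; cells with no neighbors are flagged and excluded from model
fitting, since a zero vector is not a composition.

`fit_niches()` models the composition vectors as a mixture of G Gaussians,
fitted by EM with kmeans++-style seeded initialization and restarts. Two
covariance families are provided, echoing the family search of the
established mixture software this mirrors:

* `"diagonal"` (the default): per-dimension variances with a floor of
  1e-6. Structured tissue makes whole types absent from whole regions, so
  within-component covariance matrices are singular or near-singular
  there; the diagonal family with a floor is stable and reproducible on
  exactly that kind of data.
* `"full"`: per-component full covariance matrices with a ridge floor
  (1e-6 on the diagonal). Composition vectors carry intrinsic negative
  cross-type correlations (`rho_ij = -sqrt(p_i p_j / ((1-p_i)(1-p_j)))`),
  which the diagonal family cannot represent — on strongly correlated,
  non-degenerate compositions (e.g. Dirichlet-distributed profiles) a
  diagonal mixture compensates by adding components, and only the full
  family recovers the planted component count.

BIC (`-2 log L + npar log n`, lower is better — note some mixture software
reports the opposite sign) selects G when `G = "auto"`. One subtlety
matters enormously here: profiles of nearby cells share most of their
neighbors, so neighborhood compositions are strongly spatially
autocorrelated. Treating all ~5000 profiles as independent observations
overcounts the evidence and drives BIC to carve local composition patches
into their own components — in practice the selected G then pins at the top
of the search range regardless of the true structure. The package therefore
performs model selection on a seeded, spatially thinned subset of profiles
(greedy thinning to a minimum separation of 0.7 × radius, at which two
neighborhoods are nearly disjoint and hence quasi-independent), and then
refits the selected — or user-fixed — G on all profiles to assign every
cell by maximum posterior responsibility. Fixing `G = 7` reproduces the
published lesional-skin configuration; both modes are exposed because it is
not documented whether that analysis fixed G or selected it.

Niche labels are ordered by increasing mean distance from the epidermal
boundary, so "niche 1" is always the uppermost niche and labels are
comparable across runs. `niche_summary()` returns the two standard
row-normalized views: niche proportions per condition, and cell-type
proportions per niche.

# Distance analyses

`distance_to_nearest()` computes, per sample, each cell's Euclidean
distance to the nearest cell of a target type (a sample with no target
cells yields flagged `Inf` distances — cross-sample distances are
physically meaningless). `proximal_distal_de()` contrasts query-type cells
closer than `proximal_max` against those farther than `distal_min`,
dropping the intermediate cells, via `rank_markers()`. The default bins are
30/300 µm; the source analyses also print a 10/50 µm pair in the results
text, so that pair ships as the `"narrow"` preset — the discrepancy between
the two printed threshold pairs is documented rather than resolved, and
both are accepted.

`distance_correlation_rank()` ranks genes by the Spearman correlation of
normalized expression with target distance across query cells (most
negative — most proximal-biased — first). Spearman rather than Pearson
because counts are skewed and the downstream use is ordinal; genes constant
across query cells get correlation 0 and a flag. `boundary_profile()` bins
cells by distance from the epidermal boundary line (`|y − depth|`) into
equal-width bins and reports mean expression per bin plus the Spearman
trend, the computational analog of an immunostain intensity profile.

# Module scores

`module_score()` implements gene-set scoring with expression-matched
controls: genes are ranked by dataset-average normalized expression and cut
into `n_bins = 25` equal-size bins; each set gene draws up to
`n_ctrl = 100` control genes without replacement from its bin; the score is
mean set-gene expression minus mean pooled-control expression. Control
pools exclude set genes whenever the bin contains any other gene (so a
constructed offset of δ scores exactly δ), and degrade gracefully to the
bin itself when the set covers a whole bin (scoring 0 by symmetry). Control
sampling is seeded, and scores are invariant to gene-list order and to
adding a constant to the whole matrix. `marker_mean_score()` is the
deliberately simple deconvolution-style summary — the mean normalized
expression of each label's markers per cell or pseudobulk column — with no
machine-learning step.

# The synthetic-tissue generator

`generate_tissue()` emulates what a segmented imaging-based spatial run of
lesional skin hands the pipeline:

* a tissue rectangle in image convention (origin top-left, y downward,
  µm units), with the epidermis as the band `y < epidermis_depth_um`;
* horizontal composition bands (the planted niches), each with a named
  cell-type composition; cells scatter uniformly within bands, types drawn
  i.i.d. from the band composition;
* negative-binomial counts per gene (type-specific means, dispersion 2);
  log-normal cell areas (mean 100 µm², CV 0.5);
* gradient genes whose mean is multiplied by
  `exp(±effect_size × d / height)` where `d` is the distance to the
  configured anchor (nearest neutrophil, or the epidermal boundary).

The default lesional (`"SS"`) template has seven regions: an epidermal
band; a papillary dermal band under the rete ridges (keratinocyte-adjacent,
capillary-rich); a dense neutrophil aggregate in the mid-to-upper dermis;
immune- and vessel-dominated mid-dermal bands; a mural-rich lower plexus;
and a fibroblast-rich deep dermal band. Fibroblasts are concentrated in two
niches — inside the aggregate and in the deep dermis — mirroring the
lesional architecture this template emulates, where one fibroblast niche
shares space with neutrophils and a second lies far below them. The two
chemokine analogs `CXCL1L` (decreasing with neutrophil distance, i.e.
proximal-elevated) and `CXCL12L` (increasing, distal-elevated) are
fibroblast-program genes with effect size 2.

Two geometric choices were made during design, for stated reasons:

* bands are separated by thin (60 µm) hypocellular seams — standing in for
  the basement membrane and the paucicellular collagen planes between
  dermal layers. At the 50 µm niche radius these seams make planted
  neighborhoods unambiguous: without them, a third of all profiles
  interpolate between adjacent band compositions and the planted niche
  count is not recoverable by any mixture criterion;
* the cell density is that of packed tissue (~50 neighbors per 50 µm
  ball). At low density, minority-type neighbor counts are mostly exact
  zeros, and zero-inflated fractions defeat a Gaussian mixture; at packed
  density the multinomial composition noise is approximately Gaussian.

Count depth defaults put the average cell near 100 transcripts, the order
of magnitude of targeted imaging panels.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: irregular niche shapes and gradual
niche borders, segmentation errors and doublets, probe-specific background,
sample-to-sample batch variation, within-type expression heterogeneity
beyond negative-binomial noise, and the content of any real gene panel.
Conclusions from the suite are about the correctness of the computations,
plus the recoverability of planted structure under this idealized geometry.

# Numerical choices and degenerate inputs

* EM: covariance floor 1e-6, relative log-likelihood tolerance 1e-8,
  at most 500 iterations (non-convergence is an error, not a warning);
  15 restarts per candidate G during selection (the selection subset is
  small, restarts are cheap, and they stabilize close BIC comparisons),
  5 restarts for the final full-data fit.
* Rank-sum: exact enumeration only when both groups have ≤ 8 observations
  (the enumeration is `choose(16, 8)` at worst); ties handled by mid-ranks
  in both branches; degenerate all-tied genes get p = 1.
* Annotation ties break alphabetically and are flagged rather than
  silently resolved.
* Cells at exactly the neighborhood radius are neighbors (closed ball);
  the brute-force oracle in the test suite uses the same convention.
* Empty inputs: an empty cell table passes QC as an empty table with a
  zero report; an all-filtered table is an explicit error; a sample
  without target cells yields flagged infinite distances.

# Problem sizes

The test suite and the acceptance script run the niche experiments on
5000-cell tissues with 10 replicate seeds (selection over G = 1..12), the
gradient-recovery experiment on 8000-cell tissues (≥ 1000 fibroblast query
cells), and the oracle-equivalence checks on 500-cell fixtures. These sizes
were chosen so every planted effect is comfortably detectable at desk
scale.

# A worked run

```{r, eval = FALSE}
tis <- generate_tissue(default_tissue_config("SS", n_cells = 5000, seed = 1))
cells <- mutate(tis$cells, cell_type = tis$truth$true_type)

qc <- qc_filter(cells, tis$counts)
counts <- normalize_counts(qc$counts)

prof <- neighborhood_composition(qc$cells, radius = 50)
fit <- fit_niches(prof, G = "auto", g_range = 1:12, seed = 1,
                  epidermis_depth_um = 100)
glance(fit)

dmap <- distance_to_nearest(qc$cells, "neutrophil")
de <- proximal_distal_de(counts, qc$cells, dmap, "fibroblast")
head(de)

plot_tissue(left_join(qc$cells, fit$assignment, by = "cell_id"),
            colour = factor(niche))
plot_bic(fit)
autoplot(de)
```

# Known limitations

* The niche mixture is diagonal-Gaussian over raw fractions; it does not
  model the simplex constraint, neighbor-count heteroscedasticity, or
  spatial smoothness of labels (no spatial regularization is applied, by
  design — labels are purely composition-driven).
* Marker statistics treat cells as exchangeable; there is no per-sample
  pseudobulk aggregation in the spatial contrasts.
* The generator's bands are axis-aligned; positional label ordering
  assumes the epidermis is a horizontal boundary at a known depth.
* In vitro cytokine-response signature gene lists are user input; the
  package ships no curated gene sets.
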
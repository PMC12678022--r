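# Rank-sum marker statistics: the two-group test behind cluster markers,
# per-niche fibroblast programs, and proximal/distal differential expression.

# Two-sided Wilcoxon rank-sum p-value on a single gene.
# Exact enumeration over all C(n, nA) rank assignments when both groups have
# <= `exact_max` observations (handles ties, since enumeration permutes the
# observed tied ranks); otherwise the normal approximation with the standard
# tie correction, no continuity correction.
ranksum_p <- function(a, b, exact_max = 8L) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (na <= exact_max && nb <= exact_max) {
    sums <- combn(r, na, sum)
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Rank-sum marker statistics between two cell groups
#'
#' For every gene detected (normalized value > 0) in at least `min_pct` of
#' either group, computes a two-sided Wilcoxon rank-sum test on the
#' normalized values (exact enumeration when both groups have at most 8
#' cells, tie-corrected normal approximation otherwise), the detection
#' fractions in and out of the group, and a pseudocounted log2 fold change
#' `log2((mean_a + 1) / (mean_b + 1))` of normalized means. P-values are
#' Benjamini-Hochberg adjusted over the tested genes; rows are flagged
#' `significant` when `p_adj < 0.05` and `|log2_fc| > lfc_threshold`.
#'
#' @param counts A normalized [count_matrix()].
#' @param group_a,group_b Disjoint, non-empty character vectors of cell ids
#'   (group_a is the "in" group; positive `log2_fc` means higher in A).
#' @param min_pct Minimum detection fraction in at least one group for a
#'   gene to be tested (default 0.25).
#' @param lfc_threshold Absolute log2 fold-change component of the
#'   significance flag (default 0.2).
#' @param group_label Label written into the `group` column (default "A").
#' @return A tibble of class `marker_table` with columns `gene`, `group`,
#'   `log2_fc`, `pct_in`, `pct_out`, `p_raw`, `p_adj`, `significant`,
#'   ordered by `p_adj` then decreasing `|log2_fc|`.
#' @export
rank_markers <- function(counts, group_a, group_b, min_pct = 0.25,
                         lfc_threshold = 0.2, group_label = "A") {
  need_normalized(counts, "rank_markers")
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) {
    abort("groups overlap; marker groups must be disjoint")
  }
  ia <- match(group_a, cells_of(counts))
  ib <- match(group_b, cells_of(counts))
  if (anyNA(ia) || anyNA(ib)) abort("group cell ids missing from the count matrix")

  xa <- as.matrix(counts$normalized[, ia, drop = FALSE])
  xb <- as.matrix(counts$normalized[, ib, drop = FALSE])
  pct_in <- rowMeans(xa > 0)
  pct_out <- rowMeans(xb > 0)
  tested <- which(pct_in >= min_pct | pct_out >= min_pct)
  if (length(tested) == 0L) {
    return(structure(tibble(gene = character(), group = character(),
                            log2_fc = numeric(), pct_in = numeric(),
                            pct_out = numeric(), p_raw = numeric(),
                            p_adj = numeric(), significant = logical()),
                     class = c("marker_table", class(tibble()))))
  }
  mean_a <- rowMeans(xa[tested, , drop = FALSE])
  mean_b <- rowMeans(xb[tested, , drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  p_raw <- vapply(seq_along(tested), function(i) {
    ranksum_p(xa[tested[i], ], xb[tested[i], ])
  }, numeric(1))
  p_adj <- p.adjust(p_raw, method = "BH")
  out <- tibble(
    gene = genes_of(counts)[tested],
    group = group_label,
    log2_fc = unname(lfc),
    pct_in = unname(pct_in[tested]),
    pct_out = unname(pct_out[tested]),
    p_raw = p_raw,
    p_adj = p_adj,
    significant = p_adj < 0.05 & abs(lfc) > lfc_threshold
  )
  out <- dplyr::arrange(out, .data$p_adj, dplyr::desc(abs(.data$log2_fc)))
  structure(out, class = c("marker_table", class(out)))
}

#' One-vs-rest marker statistics for every group
#'
#' Runs [rank_markers()] for each level of a grouping vector against all
#' other cells, binding the per-group tables together (the analog of
#' all-cluster marker detection).
#'
#' @param counts A normalized [count_matrix()].
#' @param groups Named character vector (or factor) of group labels, named
#'   by `cell_id`; or a tibble with `cell_id` and `group` columns.
#' @param min_pct,lfc_threshold Passed to [rank_markers()].
#' @param min_cells Skip groups with fewer cells than this (default 3).
#' @return A `marker_table` tibble spanning all groups.
#' @export
rank_markers_all <- function(counts, groups, min_pct = 0.25,
                             lfc_threshold = 0.2, min_cells = 3L) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$cell_id)
  }
  groups <- groups[!is.na(groups)]
  lev <- sort(unique(as.character(groups)))
  tabs <- purrr::map(lev, function(g) {
    in_ids <- names(groups)[groups == g]
    out_ids <- names(groups)[groups != g]
    if (length(in_ids) < min_cells || length(out_ids) < min_cells) return(NULL)
    rank_markers(counts, in_ids, out_ids, min_pct = min_pct,
                 lfc_threshold = lfc_threshold, group_label = g)
  })
  out <- dplyr::bind_rows(tabs)
  structure(out, class = c("marker_table", class(out)))
}

#' Markers significantly up in exactly one group
#'
#' Given a multi-group `marker_table` (e.g. from [rank_markers_all()]),
#' keeps rows that are significant with positive fold change, and flags
#' genes that are exclusive, i.e. significantly up in exactly one group.
#' Used to count positionally distinct expression programs (e.g. fibroblast
#' niche-programs each owning one chemokine).
#'
#' @param markers A `marker_table`.
#' @param genes Optional character vector restricting attention to a gene
#'   set (e.g. the chemokine panel).
#' @return Tibble `gene, group, log2_fc, p_adj, exclusive`.
#' @export
exclusive_markers <- function(markers, genes = NULL) {
  up <- dplyr::filter(markers, .data$significant, .data$log2_fc > 0)
  if (!is.null(genes)) up <- dplyr::filter(up, .data$gene %in% genes)
  counts_per_gene <- dplyr::count(up, .data$gene, name = "n_groups")
  up |>
    dplyr::left_join(counts_per_gene, by = "gene") |>
    dplyr::mutate(exclusive = .data$n_groups == 1L) |>
    dplyr::select("gene", "group", "log2_fc", "p_adj", "exclusive")
}
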
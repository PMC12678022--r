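# End-to-end pipeline driver: simulate/read -> qc -> normalize -> annotate
# -> niche -> distance -> score, with one global seed, per-stage derived
# seeds, and every intermediate table written to the run directory.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(condition = "SS", n_cells = 5000L, effect_size = 2,
                    sample_id = NULL),
    input = list(counts = NULL, genes = NULL, cells = NULL, truth = NULL),
    qc = list(min_counts = 20L, area_fold = 5, area_scope = "sample"),
    normalize = list(scale_factor = "median"),
    annotate = list(mode = "truth", n_pcs = 50L, resolution = 0.4,
                    n_neighbors = 20L, marker_dict = NULL),
    niche = list(radius = 50, G = "auto", g_range = c(1L, 12L),
                 query_type = "fibroblast", min_pct = 0.25,
                 lfc_threshold = 0.2),
    distance = list(target_type = "neutrophil", query_type = "fibroblast",
                    proximal_max = 30, distal_min = 300, min_pct = 0.25,
                    lfc_threshold = 0.2),
    score = list(sets = NULL, n_bins = 25L, n_ctrl = 100L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown pipeline config key: '%s'", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "sets" && key != "marker_dict") {
      if (!is.list(user[[key]])) {
        abort(sprintf("config section '%s' must be a mapping", full))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the full spatial niche-analysis pipeline
#'
#' Executes simulate (or read) -> QC -> normalization -> annotation ->
#' neighborhood/niche analysis (with per-niche query-type markers) ->
#' distance analyses -> optional module scoring, writing every intermediate
#' table, a resolved-config copy and a run log into the run directory.
#' Unknown config keys are rejected. One global seed derives fixed per-stage
#' seeds (simulate: seed; clustering: seed + 1; niche: seed + 2; scoring:
#' seed + 3), so re-running an identical config reproduces identical
#' outputs.
#'
#' Annotation modes: `"truth"` copies the generator's true types (requires a
#' simulated or truth-accompanied input); `"cluster"` runs PCA + Leiden +
#' [annotate_clusters()] with `annotate$marker_dict`.
#'
#' @param config Nested list, or path to a YAML file with the same
#'   structure. See `dermalniche:::pipeline_defaults()` for all keys and
#'   defaults.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the per-stage results (`cells`, `counts`,
#'   `qc_report`, `niche`, `niche_summary`, `niche_markers`, `distance`,
#'   `proximal_distal`, `correlation_rank`, `scores`, `config`, `paths`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  cfg$out_dir <- out_dir %||% cfg$out_dir
  if (is.null(cfg$out_dir)) abort("an output directory is required (out_dir)")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  log_path <- file.path(cfg$out_dir, "log.txt")
  cat("", file = log_path)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  emit <- function(df, file) {
    write.table(df, file.path(cfg$out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  yaml::write_yaml(purrr::map(cfg, function(x) x),
                   file.path(cfg$out_dir, "resolved_config.yaml"))

  # --- simulate or read -----------------------------------------------------
  truth <- NULL
  if (is.null(cfg$input$counts)) {
    dat <- stage("simulate", {
      tcfg <- default_tissue_config(
        condition = cfg$simulate$condition,
        n_cells = cfg$simulate$n_cells,
        effect_size = cfg$simulate$effect_size,
        sample_id = cfg$simulate$sample_id,
        seed = seed
      )
      generate_tissue(tcfg)
    })
    cells <- dat$cells; counts <- dat$counts; truth <- dat$truth
    epidermis_depth <- dat$config$epidermis_depth_um
  } else {
    dat <- stage("read", read_dataset(cfg$input$counts, cfg$input$genes,
                                      cfg$input$cells))
    cells <- dat$cells; counts <- dat$counts
    if (!is.null(cfg$input$truth)) {
      truth <- as_tibble(read.delim(cfg$input$truth))
    }
    epidermis_depth <- NULL
  }
  say("input: %d cells, %d genes", nrow(cells), nrow(counts$raw))

  # --- qc + normalize -------------------------------------------------------
  qc <- stage("qc", qc_filter(cells, counts, min_counts = cfg$qc$min_counts,
                              area_fold = cfg$qc$area_fold,
                              area_scope = cfg$qc$area_scope))
  cells <- qc$cells; counts <- qc$counts
  emit(qc$report, "qc_report.tsv")
  say("qc: %d cells retained (%d low-count, %d oversized removed)",
      qc$report$n_retained, qc$report$n_low_counts, qc$report$n_large_area)

  Matrix::writeMM(counts$raw, file.path(cfg$out_dir, "counts_filtered.mtx"))
  writeLines(genes_of(counts), file.path(cfg$out_dir, "genes.txt"))

  counts <- stage("normalize",
                  normalize_counts(counts, cfg$normalize$scale_factor))
  say("normalize: scale factor %.4g", counts$scale_factor)

  # --- annotate -------------------------------------------------------------
  cells <- stage("annotate", {
    if (cfg$annotate$mode == "truth") {
      if (is.null(truth)) abort("annotation mode 'truth' needs generator truth")
      dplyr::mutate(cells, cell_type = truth$true_type[
        match(.data$cell_id, truth$cell_id)])
    } else {
      emb <- reduce_pca(counts, n_pcs = min(cfg$annotate$n_pcs,
                                            min(dim(counts$raw)) - 1L))
      cl <- cluster_cells(emb, resolution = cfg$annotate$resolution,
                          n_neighbors = cfg$annotate$n_neighbors,
                          seed = seed + 1L)
      ann <- annotate_clusters(cl, counts, cfg$annotate$marker_dict)
      label_cells(cells, cl, ann)
    }
  })
  emit(cells, "cells_annotated.tsv")
  say("annotate: %d cell types", length(unique(cells$cell_type)))

  # --- niche ----------------------------------------------------------------
  g_range <- cfg$niche$g_range
  if (length(g_range) == 2L) g_range <- seq(g_range[1], g_range[2])
  niche <- stage("niche", {
    prof <- neighborhood_composition(cells, radius = cfg$niche$radius)
    fit <- fit_niches(prof, G = cfg$niche$G, g_range = g_range,
                      seed = seed + 2L,
                      epidermis_depth_um = epidermis_depth)
    list(profiles = prof, fit = fit)
  })
  emit(niche$fit$assignment, "niche_assignment.tsv")
  emit(niche$fit$model$bic_table, "niche_bic.tsv")
  nsum <- niche_summary(niche$fit$assignment, cells)
  emit(nsum$niche_by_condition, "niche_by_condition.tsv")
  emit(nsum$type_by_niche, "type_by_niche.tsv")
  say("niche: selected G = %d", niche$fit$model$selected_G)

  niche_markers <- stage("niche_markers", {
    q <- cells$cell_type == cfg$niche$query_type
    grp <- niche$fit$assignment$niche[match(cells$cell_id[q],
                                            niche$fit$assignment$cell_id)]
    groups <- setNames(as.character(grp), cells$cell_id[q])
    rank_markers_all(counts, groups[!is.na(grp)], min_pct = cfg$niche$min_pct,
                     lfc_threshold = cfg$niche$lfc_threshold)
  })
  emit(niche_markers, "niche_markers.tsv")
  say("niche markers: %d significant rows", sum(niche_markers$significant))

  # --- distance -------------------------------------------------------------
  dres <- stage("distance", {
    dmap <- distance_to_nearest(cells, cfg$distance$target_type)
    bins <- distance_bins(proximal_max = cfg$distance$proximal_max,
                          distal_min = cfg$distance$distal_min)
    pd <- proximal_distal_de(counts, cells, dmap, cfg$distance$query_type,
                             bins = bins, min_pct = cfg$distance$min_pct,
                             lfc_threshold = cfg$distance$lfc_threshold)
    cr <- distance_correlation_rank(counts, cells, dmap,
                                    cfg$distance$query_type)
    list(dmap = dmap, proximal_distal = pd, correlation_rank = cr)
  })
  emit(dres$dmap, "distance_map.tsv")
  emit(dres$proximal_distal, "proximal_distal_markers.tsv")
  emit(dres$correlation_rank, "distance_correlation_rank.tsv")
  say("distance: %d proximal/distal significant rows",
      sum(dres$proximal_distal$significant))

  # --- score ----------------------------------------------------------------
  scores <- NULL
  if (!is.null(cfg$score$sets)) {
    scores <- stage("score", {
      out <- tibble(cell_id = cells_of(counts))
      for (nm in names(cfg$score$sets)) {
        sc <- module_score(counts, cfg$score$sets[[nm]],
                           n_bins = cfg$score$n_bins,
                           n_ctrl = cfg$score$n_ctrl,
                           seed = seed + 3L, name = nm)
        out[[nm]] <- sc[[nm]]
      }
      out
    })
    emit(scores, "module_scores.tsv")
    say("score: %d gene sets", length(cfg$score$sets))
  }

  say("done")
  invisible(list(
    cells = cells, counts = counts, qc_report = qc$report,
    niche = niche$fit, niche_summary = nsum, niche_markers = niche_markers,
    distance = dres$dmap, proximal_distal = dres$proximal_distal,
    correlation_rank = dres$correlation_rank, scores = scores,
    config = cfg, paths = cfg$out_dir
  ))
}
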
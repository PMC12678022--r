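# Neighborhood cell-type composition and Gaussian-mixture niche fitting:
# the core spatial inference of the package.

#' Neighborhood cell-type composition per cell
#'
#' For each index cell, counts the annotated neighbors whose centroid lies
#' within `radius` micrometres (closed ball, Euclidean distance, self
#' excluded), and converts the per-type counts to fractions. Neighborhoods
#' are computed strictly within a sample; cells of different samples are
#' never neighbors. Cells with no neighbor inside the radius get a zero
#' composition and are flagged via `neighbor_count = 0` (downstream niche
#' fitting excludes them, since a zero vector is not a composition).
#'
#' @param cells Cell metadata tibble with `cell_id`, `x_um`, `y_um`,
#'   `sample_id` and a non-missing `cell_type` for every cell.
#' @param radius Neighborhood radius in micrometres (default 50, the
#'   standard niche-analysis radius).
#' @param types Optional character vector fixing the composition dimensions
#'   (defaults to the sorted set of observed cell types).
#' @return A tibble of class `neighborhood_profile` with columns `cell_id`,
#'   `sample_id`, `x_um`, `y_um`, `neighbor_count`, and one `frac_<type>`
#'   column per cell type; attributes `radius` and `types`.
#' @export
neighborhood_composition <- function(cells, radius = 50, types = NULL) {
  stopifnot(radius > 0)
  if (!"cell_type" %in% names(cells) || anyNA(cells$cell_type)) {
    bad <- if ("cell_type" %in% names(cells)) cells$cell_id[is.na(cells$cell_type)] else cells$cell_id
    abort(paste0("every cell must be annotated before composition profiling; ",
                 "unannotated: ", paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..."))
  }
  types <- types %||% sort(unique(cells$cell_type))
  out <- cells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      xy <- cbind(df$x_um, df$y_um)
      tind <- matrix(0, n, length(types), dimnames = list(NULL, types))
      tind[cbind(seq_len(n), match(df$cell_type, types))] <- 1
      counts <- matrix(0, n, length(types))
      block <- 1024L
      for (i0 in seq(1L, n, by = block)) {
        rows <- i0:min(i0 + block - 1L, n)
        within <- dist_block(xy[rows, , drop = FALSE], xy) <= radius
        within[cbind(seq_along(rows), rows)] <- FALSE  # exclude self
        counts[rows, ] <- within %*% tind
      }
      nb <- rowSums(counts)
      frac <- counts / pmax(nb, 1)
      colnames(frac) <- paste0("frac_", types)
      dplyr::bind_cols(
        tibble(cell_id = df$cell_id, sample_id = key$sample_id,
               x_um = df$x_um, y_um = df$y_um,
               neighbor_count = as.integer(nb)),
        as_tibble(frac)
      )
    }) |>
    dplyr::bind_rows()
  # restore input cell order
  out <- out[match(cells$cell_id, out$cell_id), ]
  structure(out, radius = radius, types = types,
            class = c("neighborhood_profile", class(out)))
}

# Greedy seeded spatial thinning within each sample: visit cells in random
# order, keep a cell if it is at least `min_sep` from every kept cell.
# Returns row indices into the input vectors.
thin_profiles <- function(x_um, y_um, sample_id, min_sep, seed) {
  set.seed(seed)
  kept_all <- integer(0)
  for (s in unique(sample_id)) {
    rows <- which(sample_id == s)
    ord <- rows[sample.int(length(rows))]
    kx <- numeric(0); ky <- numeric(0); kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0L ||
          min((kx - x_um[i])^2 + (ky - y_um[i])^2) >= min_sep^2) {
        kept <- c(kept, i)
        kx <- c(kx, x_um[i]); ky <- c(ky, y_um[i])
      }
    }
    kept_all <- c(kept_all, kept)
  }
  sort(kept_all)
}

profile_matrix <- function(profiles) {
  types <- attr(profiles, "types")
  m <- as.matrix(profiles[, paste0("frac_", types), drop = FALSE])
  rownames(m) <- profiles$cell_id
  m
}

#' Fit tissue niches as a Gaussian mixture over composition vectors
#'
#' Fits diagonal-covariance Gaussian mixtures to the neighborhood
#' composition vectors by EM (kmeans++-seeded starts, covariance floor
#' 1e-6). With `G = "auto"` every component count in `g_range` is fitted and
#' the model minimizing BIC (`-2 loglik + npar log n`; lower is better) is
#' selected; a numeric `G` fixes the component count (the published
#' lesional-skin configuration fixes 7).
#'
#' Profiles of nearby cells share most of their neighbors, so they are
#' strongly spatially autocorrelated; treating them as independent
#' observations overcounts the evidence and makes BIC over-segment local
#' composition patches. Model selection is therefore performed on a seeded,
#' spatially thinned subset of profiles (greedy thinning within each sample
#' to a minimum separation of `select_sep`, default 0.7 x radius, at which
#' neighborhoods are nearly disjoint); the selected or user-fixed G is then
#' refitted on all profiles, which assigns every cell the component of
#' maximum posterior responsibility.
#'
#' Niche labels are ordered by increasing mean distance from the epidermal
#' boundary when `epidermis_depth_um` is supplied (niche 1 uppermost),
#' otherwise by decreasing size. Cells without neighbors are excluded from
#' fitting and left unassigned (`NA`).
#'
#' @param profiles A `neighborhood_profile` from [neighborhood_composition()].
#' @param G `"auto"` or a fixed integer number of niches.
#' @param g_range Integer range searched when `G = "auto"` (default 1:12).
#' @param family Covariance family: `"diagonal"` (default; stable on the
#'   near-degenerate compositions of structured tissue, where types are
#'   absent from whole regions) or `"full"` (ridge-regularized full
#'   covariances, which capture the negative correlations intrinsic to
#'   compositional data and are preferable for strongly correlated,
#'   non-degenerate compositions).
#' @param seed Integer seed for the EM starts and the selection thinning.
#' @param epidermis_depth_um Optional epidermal boundary depth used to
#'   order niche labels positionally.
#' @param select_sep Minimum spatial separation (micrometres) of the
#'   profiles used for BIC model selection; `NULL` uses 0.7 x the profile
#'   radius.
#' @param select_nstart Number of seeded EM starts per candidate G during
#'   model selection (the selection subset is small, so generous restarts
#'   are cheap and stabilize the BIC comparison).
#' @param nstart Number of EM starts for the final full-data fit.
#' @param max_iter,tol EM control parameters.
#' @return An object of class `niche_fit`: list with
#'   * `model` (class `niche_model`): component `means`, `vars`, `weights`
#'     (rows ordered as the final labels), `bic_table` (tibble `G`, `bic`,
#'     `loglik`), `selected_G`, `loglik_trace`, `seed`;
#'   * `assignment`: tibble `cell_id`, `niche` (integer, `NA` for
#'     neighborless cells), `responsibility`.
#' @export
fit_niches <- function(profiles, G = "auto", g_range = 1:12, seed = 1L,
                       epidermis_depth_um = NULL,
                       family = c("diagonal", "full"), select_sep = NULL,
                       select_nstart = 15L, nstart = 5L,
                       max_iter = 500L, tol = 1e-8) {
  family <- match.arg(family)
  fit_one <- if (family == "diagonal") fit_gmm_diag else fit_gmm_full
  usable <- profiles$neighbor_count > 0
  x <- profile_matrix(profiles)[usable, , drop = FALSE]
  if (nrow(x) < 10L) abort("need at least 10 profiled cells with neighbors")
  check_convergence <- function(fits, gs) {
    bad <- !vapply(fits, `[[`, logical(1), "converged")
    if (any(bad)) {
      abort(sprintf(
        "EM did not converge within %d iterations for G = %s (final loglik %s); increase max_iter or loosen tol",
        max_iter, paste(gs[bad], collapse = ", "),
        paste(sprintf("%.3f", vapply(fits[bad], `[[`, numeric(1), "loglik")),
              collapse = ", ")))
    }
  }
  if (identical(G, "auto")) {
    select_sep <- select_sep %||% (0.7 * attr(profiles, "radius"))
    sel_rows <- thin_profiles(profiles$x_um[usable], profiles$y_um[usable],
                              profiles$sample_id[usable], select_sep, seed)
    xs <- x[sel_rows, , drop = FALSE]
    g_range <- g_range[g_range >= 1 & g_range <= nrow(xs) / 10]
    sel_fits <- lapply(g_range, function(g)
      fit_one(xs, g, seed = seed, nstart = select_nstart,
              max_iter = max_iter, tol = tol))
    check_convergence(sel_fits, g_range)
    bic_table <- tibble(
      G = g_range,
      bic = vapply(sel_fits, `[[`, numeric(1), "bic"),
      loglik = vapply(sel_fits, `[[`, numeric(1), "loglik"),
      n_fit = nrow(xs)
    )
    sel_G <- g_range[which.min(bic_table$bic)]
  } else {
    stopifnot(is.numeric(G), length(G) == 1L, G >= 1)
    sel_G <- as.integer(G)
    bic_table <- NULL
  }
  # final model: selected G refitted on all usable profiles
  best <- fit_one(x, sel_G, seed = seed, nstart = nstart,
                  max_iter = max_iter, tol = tol)
  check_convergence(list(best), sel_G)
  if (is.null(bic_table)) {
    bic_table <- tibble(G = sel_G, bic = best$bic, loglik = best$loglik,
                        n_fit = nrow(x))
  }

  comp <- max.col(best$responsibilities)
  resp <- best$responsibilities[cbind(seq_along(comp), comp)]

  # order labels positionally (uppermost niche first) or by size
  if (!is.null(epidermis_depth_um) && "y_um" %in% names(profiles)) {
    edist <- epidermis_distance(profiles$y_um[usable], epidermis_depth_um)
    key <- vapply(seq_len(sel_G), function(g) {
      if (any(comp == g)) mean(edist[comp == g]) else Inf
    }, numeric(1))
    ord <- order(key)
  } else {
    ord <- order(-tabulate(comp, sel_G))
  }
  relabel <- integer(sel_G); relabel[ord] <- seq_len(sel_G)

  assignment <- tibble(
    cell_id = profiles$cell_id,
    niche = NA_integer_,
    responsibility = NA_real_
  )
  assignment$niche[usable] <- relabel[comp]
  assignment$responsibility[usable] <- resp

  model <- structure(
    list(
      means = best$means[ord, , drop = FALSE],
      vars = best$vars[ord, , drop = FALSE],
      covs = if (!is.null(best$covs)) best$covs[ord, , , drop = FALSE],
      weights = best$weights[ord],
      types = attr(profiles, "types"),
      family = family,
      bic_table = bic_table,
      selected_G = sel_G,
      loglik = best$loglik,
      loglik_trace = best$trace,
      seed = seed
    ),
    class = "niche_model"
  )
  structure(list(model = model, assignment = assignment), class = "niche_fit")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("<niche_model> %d niches over %d cell types (BIC %.1f, loglik %.1f)\n",
              x$selected_G, length(x$types),
              min(x$bic_table$bic), x$loglik))
  invisible(x)
}

#' @export
print.niche_fit <- function(x, ...) {
  print(x$model)
  n_ass <- sum(!is.na(x$assignment$niche))
  cat(sprintf("  %d of %d cells assigned\n", n_ass, nrow(x$assignment)))
  invisible(x)
}

#' Summarize niches by condition and by cell type
#'
#' @param assignment Niche assignment tibble (`cell_id`, `niche`), e.g.
#'   `fit$assignment` from [fit_niches()].
#' @param cells Cell metadata with `cell_id`, `condition`, `cell_type`.
#' @return A list of two row-normalized long tibbles:
#'   `niche_by_condition` (`condition`, `niche`, `proportion`; proportions
#'   sum to 1 within each condition) and `type_by_niche` (`niche`,
#'   `cell_type`, `proportion`; sum to 1 within each niche).
#' @export
niche_summary <- function(assignment, cells) {
  joined <- assignment |>
    dplyr::filter(!is.na(.data$niche)) |>
    dplyr::inner_join(cells, by = "cell_id")
  niche_by_condition <- joined |>
    dplyr::count(.data$condition, .data$niche) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("condition", "niche", "proportion")
  type_by_niche <- joined |>
    dplyr::count(.data$niche, .data$cell_type) |>
    dplyr::group_by(.data$niche) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("niche", "cell_type", "proportion")
  list(niche_by_condition = niche_by_condition, type_by_niche = type_by_niche)
}
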
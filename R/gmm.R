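# Diagonal-covariance Gaussian mixture fitted by EM, the engine behind
# niche clustering of neighborhood composition vectors. Initialization is
# kmeans++-style and seeded; the covariance floor keeps near-degenerate
# composition dimensions from collapsing the likelihood.

kmeanspp_centers <- function(x, G) {
  n <- nrow(x)
  centers <- matrix(NA_real_, G, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (G > 1) {
    d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
    for (g in 2:G) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[g, ] <- x[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[g, ])^2))
    }
  }
  centers
}

# log N(x | mu, diag(var)) for all rows of x and all components
gmm_logdens <- function(x, means, vars) {
  n <- nrow(x); G <- nrow(means)
  ld <- matrix(0, n, G)
  for (g in seq_len(G)) {
    v <- vars[g, ]
    ld[, g] <- -0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(sweep(x, 2L, means[g, ])^2, 2L, v, `/`))
  }
  ld
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# One EM run from one kmeans++ start. Returns NULL on degenerate collapse.
gmm_em_once <- function(x, G, max_iter, tol, var_floor) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, G)
  assign0 <- max.col(-dist_block(x, centers))  # nearest center
  means <- matrix(0, G, d); vars <- matrix(var_floor, G, d)
  weights <- numeric(G)
  for (g in seq_len(G)) {
    rows <- x[assign0 == g, , drop = FALSE]
    weights[g] <- max(nrow(rows), 1) / n
    if (nrow(rows) == 0L) {
      means[g, ] <- centers[g, ]
    } else {
      means[g, ] <- colMeans(rows)
      vars[g, ] <- pmax(apply(rows, 2L, stats::var), var_floor)
    }
  }
  vars[!is.finite(vars)] <- var_floor
  weights <- weights / sum(weights)

  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- sweep(gmm_logdens(x, means, vars), 2L, log(weights), `+`)
    lse <- logsumexp_rows(ld)
    new_loglik <- sum(lse)
    r <- exp(ld - lse)
    # M-step
    ng <- colSums(r)
    ng <- pmax(ng, 1e-10)
    weights <- ng / n
    means <- (crossprod(r, x)) / ng
    ex2 <- (crossprod(r, x^2)) / ng
    vars <- pmax(ex2 - means^2, var_floor)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && abs(new_loglik - loglik) <=
        tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  ld <- sweep(gmm_logdens(x, means, vars), 2L, log(weights), `+`)
  lse <- logsumexp_rows(ld)
  list(means = means, vars = vars, weights = weights,
       loglik = sum(lse), trace = trace, converged = converged,
       responsibilities = exp(ld - lse), n_iter = length(trace))
}

# Best of `nstart` seeded EM runs; BIC under the lower-is-better convention
# -2 loglik + npar log n with npar = (G - 1) + 2 G d.
fit_gmm_diag <- function(x, G, seed = 1L, nstart = 3L, max_iter = 300L,
                         tol = 1e-8, var_floor = 1e-6) {
  set.seed(seed + 7L * G)
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- gmm_em_once(x, G, max_iter, tol, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!all(is.finite(best$trace))) {
    abort(sprintf(
      "EM for G = %d did not produce a finite log-likelihood (n = %d, d = %d)",
      G, nrow(x), ncol(x)))
  }
  npar <- (G - 1) + 2 * G * ncol(x)
  best$G <- G
  best$bic <- -2 * best$loglik + npar * log(nrow(x))
  best
}

# Full-covariance variant: per-component covariance matrices with a ridge
# floor (ridge * I added after every M-step) so structurally degenerate
# composition dimensions cannot make a component singular. Captures the
# negative correlations intrinsic to compositional data that the diagonal
# family cannot. npar = (G - 1) + G (d + d (d + 1) / 2).
gmm_full_em_once <- function(x, G, max_iter, tol, ridge) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, G)
  assign0 <- max.col(-dist_block(x, centers))
  means <- matrix(0, G, d)
  covs <- array(0, c(G, d, d))
  weights <- numeric(G)
  pooled <- stats::var(as.vector(x))
  for (g in seq_len(G)) {
    rows <- x[assign0 == g, , drop = FALSE]
    weights[g] <- max(nrow(rows), 1) / n
    means[g, ] <- if (nrow(rows)) colMeans(rows) else centers[g, ]
    covs[g, , ] <- if (nrow(rows) > d) stats::cov(rows) + diag(ridge, d)
                   else diag(pooled + ridge, d)
  }
  weights <- weights / sum(weights)

  comp_logdens <- function() {
    ld <- matrix(0, n, G)
    for (g in seq_len(G)) {
      ch <- chol(covs[g, , ])
      z <- forwardsolve(t(ch), t(x) - means[g, ])
      ld[, g] <- -0.5 * d * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * colSums(z^2) + log(weights[g])
    }
    ld
  }

  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- comp_logdens()
    lse <- logsumexp_rows(ld)
    new_loglik <- sum(lse)
    r <- exp(ld - lse)
    ng <- pmax(colSums(r), 1e-10)
    weights <- ng / n
    means <- crossprod(r, x) / ng
    for (g in seq_len(G)) {
      xc <- sweep(x, 2L, means[g, ])
      covs[g, , ] <- crossprod(xc * r[, g], xc) / ng[g] + diag(ridge, d)
    }
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && abs(new_loglik - loglik) <=
        tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  ld <- comp_logdens()
  lse <- logsumexp_rows(ld)
  list(means = means, vars = t(apply(covs, 1, diag)), covs = covs,
       weights = weights, loglik = sum(lse), trace = trace,
       converged = converged, responsibilities = exp(ld - lse),
       n_iter = length(trace))
}

fit_gmm_full <- function(x, G, seed = 1L, nstart = 3L, max_iter = 300L,
                         tol = 1e-8, ridge = 1e-6) {
  set.seed(seed + 7L * G)
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- gmm_full_em_once(x, G, max_iter, tol, ridge)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!all(is.finite(best$trace))) {
    abort(sprintf(
      "EM for G = %d did not produce a finite log-likelihood (n = %d, d = %d)",
      G, nrow(x), ncol(x)))
  }
  d <- ncol(x)
  npar <- (G - 1) + G * (d + d * (d + 1) / 2)
  best$G <- G
  best$bic <- -2 * best$loglik + npar * log(nrow(x))
  best
}
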
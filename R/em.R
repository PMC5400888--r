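# Diagonal Gaussian mixture fit by expectation maximization, with
# cross-validated forward search over the number of components. Count-valued
# feature families (n-grams, terminology) are log1p-transformed before
# fitting; style features enter raw. Per-feature independence (diagonal
# covariance) keeps the model desk-scale on thousands of n-gram columns.

# Apply the modelling transform: log1p on count families, raw otherwise.
# Matrices without a families attribute are taken as continuous.
.em_transform <- function(X) {
  fam <- attr(X, "families")
  if (is.null(fam)) return(unclass(X))
  Z <- unclass(X)
  cnt <- fam %in% c("F2", "F3", "F4")
  if (any(cnt)) Z[, cnt] <- log1p(Z[, cnt, drop = FALSE])
  attr(Z, "families") <- NULL
  Z
}

# n x K matrix of log N(x | mu_k, diag(var_k)) + log w_k.
.log_component_density <- function(Z, Z2, mu, v, logw) {
  iv <- 1 / v                                     # d x K
  A <- Z2 %*% iv                                  # sum x^2 / var
  B <- Z %*% (mu * iv)                            # sum x mu / var
  cst <- -0.5 * colSums(log(2 * pi * v)) - 0.5 * colSums(mu^2 * iv)
  sweep(-0.5 * A + B, 2L, cst + logw, `+`)
}

.logsumexp_rows <- function(M) {
  mx <- do.call(pmax, c(lapply(asplit(M, 2L), as.vector), list(-Inf)))
  mx + log(rowSums(exp(M - mx)))
}

# One EM run from given responsibilities; returns model + trace.
# Component variances are shrunk toward the global per-feature variance with
# `var_prior` pseudo-observations (inverse-gamma prior mean), which keeps
# held-out likelihoods finite and well behaved on sparse count features
# where a component can otherwise collapse onto a constant column.
.em_run <- function(Z, Z2, K, resp, tol, max_iter, scale_floor,
                    var_prior = 2, var_floor_frac = 0.08) {
  n <- nrow(Z)
  v_global <- pmax(colMeans(Z2) - colMeans(Z)^2, scale_floor)
  v_floor <- pmax(var_floor_frac * v_global, scale_floor)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    Nk <- pmax(colSums(resp), 1e-10)
    w <- Nk / sum(Nk)
    mu <- sweep(crossprod(Z, resp), 2L, Nk, `/`)                # d x K
    v <- sweep(crossprod(Z2, resp), 2L, Nk, `/`) - mu^2
    v <- sweep(sweep(v, 2L, Nk, `*`), 1L, var_prior * v_global, `+`)
    v <- sweep(v, 2L, Nk + var_prior, `/`)
    v <- pmax(v, v_floor)
    # E-step
    logd <- .log_component_density(Z, Z2, mu, v, log(w))
    lse <- .logsumexp_rows(logd)
    ll <- sum(lse)
    if (!is.finite(ll)) stop("EM: non-finite log-likelihood (K=", K, ")")
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) break
    ll_prev <- ll
  }
  list(weights = w, mu = mu, var = v, resp = resp,
       log_likelihood = ll, ll_trace = ll_trace, n_iter = iter)
}

.hard_resp <- function(cluster, K) {
  r <- matrix(1e-3, length(cluster), K)
  r[cbind(seq_along(cluster), cluster)] <- 1
  r / rowSums(r)
}

.safe_kmeans <- function(M, K, nstart = 10L) {
  km <- tryCatch(
    stats::kmeans(M, centers = K, nstart = nstart, iter.max = 50L),
    error = function(e) NULL)
  if (is.null(km)) NULL else km$cluster
}

# Latent-semantic embedding of the cosine geometry: top-m left singular
# subspace of the row-normalized data, computed by randomized subspace
# iteration (a few matrix products instead of a full decomposition, which
# matters inside cross-validation).
.lsa_embedding <- function(Z, m, n_iter = 15L) {
  rn <- Z / pmax(sqrt(rowSums(Z^2)), 1e-12)
  m <- min(m, nrow(rn) - 1L, ncol(rn))
  V <- matrix(stats::rnorm(ncol(rn) * m), ncol = m)
  U <- NULL
  for (i in seq_len(n_iter)) {
    U <- qr.Q(qr(rn %*% V))
    V <- qr.Q(qr(crossprod(rn, U)))
  }
  rn %*% V
}

# Responsibility initializations: k-means partitions of the latent-semantic
# embedding (raw and row-renormalized, the latter approximating a spectral
# partition of the cosine affinity), then random soft splits.
# High-dimensional mixtures have many poor local optima; the restarts are
# scored by final log-likelihood in the caller.
.em_inits <- function(Z, K, n_init, embedding = NULL) {
  n <- nrow(Z)
  if (K == 1L) return(list(matrix(1, n, 1L)))
  inits <- list()
  add <- function(cl) {
    if (!is.null(cl) && length(unique(cl)) == K) {
      inits[[length(inits) + 1L]] <<- .hard_resp(cl, K)
    }
  }
  # at small n the full-dimensional partitions are affordable and find
  # better basins than the reduced embedding
  if (n <= 600L) {
    rn <- Z / pmax(sqrt(rowSums(Z^2)), 1e-12)
    add(.safe_kmeans(rn, K))
    if (length(inits) < n_init && n <= ncol(Z)) {
      S <- tcrossprod(rn)
      diag(S) <- 0
      S[S < 0] <- 0
      dinv <- 1 / sqrt(pmax(rowSums(S), 1e-12))
      ev <- eigen(S * outer(dinv, dinv), symmetric = TRUE)
      sp <- ev$vectors[, seq_len(K), drop = FALSE]
      sp <- sp / pmax(sqrt(rowSums(sp^2)), 1e-12)
      add(.safe_kmeans(sp, K, nstart = 20L))
    }
  }
  if (length(inits) < n_init) {
    if (is.null(embedding)) {
      embedding <- .lsa_embedding(Z, max(2L * K, 8L))
    }
    E <- embedding[, seq_len(min(max(2L * K, 8L), ncol(embedding))),
                   drop = FALSE]
    add(.safe_kmeans(E, K))
    if (length(inits) < n_init) {
      En <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
      add(.safe_kmeans(En, K))
    }
  }
  while (length(inits) < n_init) {
    r <- matrix(stats::runif(n * K, min = 0.05), n, K)
    inits[[length(inits) + 1L]] <- r / rowSums(r)
  }
  inits
}

#' Fit a diagonal Gaussian mixture by EM
#'
#' Count-family columns (F2/F3/F4) of a feature matrix are log1p-transformed;
#' style columns enter raw. The model assumes per-feature independence
#' (diagonal covariance) with a per-feature variance floor. Several
#' initializations are run (a k-means seeding plus random responsibility
#' draws) and the fit with the best training log-likelihood is kept. The
#' log-likelihood is non-decreasing across EM iterations; the trace is
#' returned for inspection.
#'
#' @param X Numeric matrix (units x features), e.g. from
#'   [build_feature_matrix()].
#' @param K Number of mixture components (>= 1).
#' @param seed Integer seed controlling initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per run (default 200).
#' @param n_init Number of initializations (default 5).
#' @param scale_floor Hard variance floor per feature (default 1e-6).
#' @param var_prior Strength (pseudo-observations) of the shrinkage of each
#'   component's variances toward the global per-feature variance (default
#'   2; 0 with `var_floor_frac = 0` gives plain maximum-likelihood EM, whose
#'   log-likelihood trace is exactly non-decreasing).
#' @param var_floor_frac Relative variance floor: each component variance is
#'   kept at or above this fraction of the global per-feature variance
#'   (default 0.08). Guards against component collapse on sparse count
#'   columns while leaving informative columns discriminative.
#' @return List with `model` (an `em_mixture`: `K`, `weights`, `mu`, `var`,
#'   `log_likelihood`, `ll_trace`, `n_iter`) and `assignment`
#'   (`unit_ids`, `posterior` with rows summing to 1, `labels` = argmax
#'   posterior, ties to the lowest index).
#' @export
fit_em <- function(X, K, seed = 1L, tol = 1e-6, max_iter = 200L,
                   n_init = 5L, scale_floor = 1e-6, var_prior = 2,
                   var_floor_frac = 0.08) {
  stopifnot(K >= 1L, nrow(X) >= K)
  Z <- .em_transform(X)
  Z2 <- Z^2
  set.seed(seed)
  best <- NULL
  for (resp0 in .em_inits(Z, K, n_init)) {
    fit <- .em_run(Z, Z2, K, resp0, tol, max_iter, scale_floor, var_prior,
                   var_floor_frac)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  posterior <- best$resp
  labels <- max.col(posterior, ties.method = "first")
  model <- structure(
    list(K = K, weights = best$weights, mu = best$mu, var = best$var,
         log_likelihood = best$log_likelihood, ll_trace = best$ll_trace,
         n_iter = best$n_iter),
    class = "em_mixture")
  assignment <- list(unit_ids = rownames(X), posterior = posterior,
                     labels = labels)
  list(model = model, assignment = assignment)
}

#' @export
print.em_mixture <- function(x, ...) {
  cat(sprintf("<em_mixture> K=%d, logLik=%.3f, %d iteration(s)\n",
              x$K, x$log_likelihood, x$n_iter))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Held-out log-density of points under a fitted mixture
#'
#' @param model An `em_mixture`.
#' @param Z Transformed data matrix (same transform as training).
#' @return Numeric vector of per-point log-likelihoods.
#' @keywords internal
.em_loglik <- function(model, Z) {
  .logsumexp_rows(.log_component_density(Z, Z^2, model$mu, model$var,
                                         log(model$weights)))
}

#' Select the number of mixture components by cross-validated EM
#'
#' Forward search over K = 1, 2, ...: for each K the mean held-out
#' log-likelihood per unit over `folds` cross-validation folds is computed;
#' the search stops at the first K that fails to improve on K - 1 and
#' returns K - 1 (or `k_max` if the score improves all the way up).
#'
#' @param X Feature matrix.
#' @param k_max Largest K to consider (default 6).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed (controls fold assignment and EM inits).
#' @param n_init Initializations per EM fit inside CV (default 2; the final
#'   model is normally refit with [fit_em()]'s default).
#' @param tol,max_iter,scale_floor,var_prior,var_floor_frac Passed to the
#'   internal EM runs; see [fit_em()].
#' @return List: `k` (selected), `cv_table` (tibble K, cv_loglik).
#' @export
select_k <- function(X, k_max = 6L, folds = 10L, seed = 1L, n_init = 2L,
                     tol = 1e-6, max_iter = 200L, scale_floor = 1e-6,
                     var_prior = 2, var_floor_frac = 0.08) {
  stopifnot(k_max >= 1L, folds >= 2L, nrow(X) >= folds)
  Z <- .em_transform(X)
  n <- nrow(Z)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  # the initialization embedding is computed once per fold and shared
  # across candidate K (its leading columns are what each K uses)
  emb <- vector("list", folds)
  for (f in seq_len(folds)) {
    set.seed(seed * 1000L + f)
    emb[[f]] <- .lsa_embedding(Z[fold_id != f, , drop = FALSE],
                               max(2L * k_max, 8L))
  }
  cv <- numeric(0)
  best_k <- 1L
  for (K in seq_len(k_max)) {
    fold_ll <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- Z[fold_id != f, , drop = FALSE]
      te <- Z[fold_id == f, , drop = FALSE]
      if (nrow(tr) < K) { fold_ll[f] <- -Inf; next }
      tr2 <- tr^2
      set.seed(seed * 1000L + K * 100L + f)
      best <- NULL
      for (resp0 in .em_inits(tr, K, n_init, embedding = emb[[f]])) {
        fit <- .em_run(tr, tr2, K, resp0, tol, max_iter, scale_floor,
                       var_prior, var_floor_frac)
        if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
          best <- fit
        }
      }
      model <- list(mu = best$mu, var = best$var, weights = best$weights)
      fold_ll[f] <- mean(.em_loglik(model, te))
    }
    cv[K] <- mean(fold_ll)
    if (K > 1L && cv[K] <= cv[K - 1L]) break
    best_k <- K
  }
  list(k = best_k,
       cv_table = tibble::tibble(K = seq_along(cv), cv_loglik = cv))
}
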
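# External partition agreement (pair-counting) and the two-sample t test
# used to compare clusters.

#' Pair-counting agreement between two partitions
#'
#' Over all unordered pairs of units, with `a` = pairs co-clustered in both
#' partitions, `b` = co-clustered in the reference only, `c` = co-clustered
#' in the prediction only, and `d` = in neither:
#' Rand = (a + d) / (a + b + c + d), Jaccard = a / (a + b + c),
#' Fowlkes-Mallows = a / sqrt((a + b)(a + c)) (0 when a = 0). All three are
#' invariant to relabeling of either partition and equal 1 exactly when the
#' partitions coincide up to relabeling.
#'
#' @param pred_labels,ref_labels Equal-length label vectors (length >= 2).
#' @return List with `rand`, `jaccard`, `fm`, each in `[0, 1]`.
#' @export
partition_metrics <- function(pred_labels, ref_labels) {
  if (length(pred_labels) != length(ref_labels)) {
    stop("label vectors differ in length")
  }
  n <- length(pred_labels)
  stopifnot(n >= 2L)
  ct <- table(pred_labels, ref_labels)
  ch2 <- function(x) x * (x - 1) / 2
  total <- ch2(n)
  a <- sum(ch2(ct))
  a_plus_c <- sum(ch2(rowSums(ct)))   # co-clustered in prediction
  a_plus_b <- sum(ch2(colSums(ct)))   # co-clustered in reference
  b <- a_plus_b - a
  c <- a_plus_c - a
  d <- total - a - b - c
  list(
    rand = (a + d) / total,
    jaccard = if (a + b + c > 0) a / (a + b + c) else 1,
    fm = if (a == 0) 0 else a / sqrt(a_plus_b * a_plus_c)
  )
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value (a thin wrapper over [stats::t.test()]). When
#' both samples are constant with equal means the degenerate case returns
#' t = 0, p = 1.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- tryCatch(
    stats::t.test(a, b, var.equal = FALSE),
    error = function(e) {
      if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
        return(list(statistic = c(t = 0), parameter = c(df = NA_real_),
                    p.value = 1))
      }
      stop(e)
    })
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pairwise cluster-difference t tests over posterior-weighted feature means
#'
#' For every pair of mixture components, compares the units' per-feature
#' values weighted by their posterior membership: for each unit the
#' posterior-weighted feature mean is computed, then a Welch t test compares
#' the hard-assigned members of the two clusters on that summary.
#'
#' @param X Feature matrix used for the fit.
#' @param assignment Assignment list from [fit_em()].
#' @return Tibble with `cluster_a`, `cluster_b`, `t`, `df`, `p`.
#' @export
cluster_t_tests <- function(X, assignment) {
  Z <- .em_transform(X)
  summary_stat <- rowMeans(Z)
  labels <- assignment$labels
  ks <- sort(unique(labels))
  out <- list()
  for (i in seq_along(ks)) {
    for (j in seq_along(ks)) {
      if (j <= i) next
      a <- summary_stat[labels == ks[i]]
      b <- summary_stat[labels == ks[j]]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- two_sample_t(a, b)
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster_a = ks[i], cluster_b = ks[j],
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(cluster_a = integer(), cluster_b = integer(),
                          t = numeric(), df = numeric(), p = numeric()))
  }
  dplyr::bind_rows(out)
}
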
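# Cluster keyword extraction: frequency x inverse cluster-rank scoring.
# For term w and cluster C_i among N clusters,
#   score(w, C_i) = f(w, C_i) * ln( N / m ),
# where f(w, C_i) is the raw frequency of w over all texts in C_i and m is
# the number of clusters whose frequency of w is >= f(w, C_i). The cluster
# itself is always counted, so m >= 1; a term with the same frequency in
# every cluster scores 0 everywhere, and a strict maximum scores
# f * ln(N).

#' Score terms per cluster by frequency times inverse cluster rank
#'
#' @param freq_by_cluster Either a named list/matrix mapping each term to its
#'   per-cluster frequency vector: a numeric matrix with terms as rows and N
#'   cluster columns, or a list of named numeric vectors of length N.
#' @param N Number of clusters; must match the vector length / column count.
#' @return Tibble with `term`, `cluster` (1-based), `freq`, `score`.
#' @export
keyword_score <- function(freq_by_cluster, N = NULL) {
  if (is.list(freq_by_cluster) && !is.data.frame(freq_by_cluster)) {
    freq_by_cluster <- do.call(rbind, freq_by_cluster)
  }
  F <- as.matrix(freq_by_cluster)
  if (is.null(N)) N <- ncol(F)
  stopifnot(N >= 1L, ncol(F) == N, all(F >= 0))
  if (is.null(rownames(F))) rownames(F) <- paste0("term", seq_len(nrow(F)))
  # m[w, i] = #{ j : f(w, C_j) >= f(w, C_i) }
  scores <- matrix(0, nrow(F), N, dimnames = dimnames(F))
  for (i in seq_len(N)) {
    m <- rowSums(F >= F[, i])
    scores[, i] <- F[, i] * log(N / m)
  }
  tibble::tibble(
    term = rep(rownames(F), N),
    cluster = rep(seq_len(N), each = nrow(F)),
    freq = as.vector(F),
    score = as.vector(scores)
  )
}

#' Per-cluster term frequencies from texts and cluster labels
#'
#' Counts each n-gram's total occurrences over all texts assigned to each
#' cluster — the f(w, C_i) input to [keyword_score()].
#'
#' @param texts Character vector of unit texts (merged member documents for
#'   the stakeholder task, informational messages for the topic task).
#' @param labels Cluster label per text.
#' @param ngram_range Integer pair within `[1, 3]`.
#' @param min_total_freq Drop terms whose total frequency over all clusters
#'   is below this (default 2; keeps the score table small).
#' @return Numeric matrix, terms x clusters (columns ordered by sorted label).
#' @export
cluster_term_frequencies <- function(texts, labels, ngram_range = c(1L, 3L),
                                     min_total_freq = 2L) {
  stopifnot(length(texts) == length(labels))
  ks <- sort(unique(labels))
  toks <- tokenize(texts, simplify = FALSE)
  counts_by_cluster <- lapply(ks, function(k) {
    grams <- unlist(lapply(toks[labels == k], extract_ngrams,
                           ngram_range = ngram_range))
    if (is.null(grams)) return(stats::setNames(integer(0), character(0)))
    tapply(unname(grams), names(grams), sum)
  })
  vocab <- sort(unique(unlist(lapply(counts_by_cluster, names))))
  F <- matrix(0, length(vocab), length(ks),
              dimnames = list(vocab, as.character(ks)))
  for (j in seq_along(ks)) {
    cc <- counts_by_cluster[[j]]
    if (length(cc)) F[names(cc), j] <- as.numeric(cc)
  }
  F[rowSums(F) >= min_total_freq, , drop = FALSE]
}

#' Top-ranked keywords of one cluster
#'
#' Removes terms whose tokens are all stopwords (so single stopwords go, but
#' content-bearing phrases such as "thank you" survive), then ranks by
#' descending score, breaking ties by higher frequency and then
#' lexicographically, and returns at most `k` terms.
#'
#' @param scores Tibble from [keyword_score()].
#' @param cluster Cluster index to report.
#' @param k Maximum number of keywords (default 20).
#' @param stoplist Character vector of stopwords
#'   (default [default_stopwords()]).
#' @return Tibble with `rank`, `term`, `freq`, `score`.
#' @export
top_keywords <- function(scores, cluster, k = 20L,
                         stoplist = default_stopwords()) {
  stopifnot(k >= 1L)
  s <- scores[scores$cluster == cluster & scores$score > 0, , drop = FALSE]
  if (nrow(s) > 0L && length(stoplist) > 0L) {
    all_stop <- vapply(strsplit(s$term, " ", fixed = TRUE),
                       function(tk) all(tk %in% stoplist), logical(1L))
    s <- s[!all_stop, , drop = FALSE]
  }
  ord <- order(-s$score, -s$freq, s$term)
  s <- s[ord, , drop = FALSE][seq_len(min(k, nrow(s))), , drop = FALSE]
  tibble::tibble(rank = seq_len(nrow(s)), term = s$term,
                 freq = s$freq, score = s$score)
}
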
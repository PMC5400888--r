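# Feature extraction: unit x feature matrices over four feature families.
#   F1 style      message_count, avg sentences/message, words/message
#                 (member documents only)
#   F2 ngrams     word unigrams/bigrams/trigrams
#   F3 medical    medical terminology counts (term lexicon, semtype-coded)
#   F4 kinship    kinship terminology counts (famg)
# Stakeholder clustering runs over member documents with F1-F4; topic
# clustering runs over informational messages with F2+F3.

#' Feature extraction specification
#'
#' @param families Subset of `c("F1", "F2", "F3", "F4")`: writing style,
#'   word n-grams, medical terminology, kinship terminology.
#' @param ngram_range Integer pair within `[1, 3]`: smallest and largest n.
#' @param min_doc_freq Keep an n-gram column only if it occurs in at least
#'   this many units (default 3).
#' @param vocabulary_cap Keep at most this many n-gram columns, by descending
#'   total frequency, ties broken lexicographically (default 5000).
#' @param weighting `"raw_count"` (default) or `"relative_freq"` (each unit's
#'   F2 block rescaled to sum to 1 when nonempty).
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(families = c("F1", "F2", "F3", "F4"),
                         ngram_range = c(1L, 3L),
                         min_doc_freq = 3L,
                         vocabulary_cap = 5000L,
                         weighting = c("raw_count", "relative_freq")) {
  weighting <- match.arg(weighting)
  families <- match.arg(families, c("F1", "F2", "F3", "F4"),
                        several.ok = TRUE)
  stopifnot(length(ngram_range) == 2L,
            ngram_range[1] >= 1L, ngram_range[2] <= 3L,
            ngram_range[1] <= ngram_range[2],
            min_doc_freq >= 1L)
  structure(list(families = families,
                 ngram_range = as.integer(ngram_range),
                 min_doc_freq = as.integer(min_doc_freq),
                 vocabulary_cap = if (is.null(vocabulary_cap)) NULL
                                  else as.integer(vocabulary_cap),
                 weighting = weighting),
            class = "feature_spec")
}

#' Writing-style features of a member document
#'
#' @param doc One row (or several) of the tibble from [merge_by_author()].
#' @return Tibble with `message_count`, `avg_sentences_per_message`,
#'   `words_per_message`.
#' @export
extract_style_features <- function(doc) {
  tibble::tibble(
    message_count = as.numeric(doc$message_count),
    avg_sentences_per_message = doc$sentence_count / doc$message_count,
    words_per_message = doc$word_count / doc$message_count
  )
}

#' Count contiguous word n-grams
#'
#' @param tokens Character vector of normalized tokens.
#' @param ngram_range Integer pair `c(min_n, max_n)` within `[1, 3]`.
#' @return Named integer vector of n-gram counts; tokens inside an n-gram are
#'   joined with a single space.
#' @export
extract_ngrams <- function(tokens, ngram_range = c(1L, 3L)) {
  stopifnot(ngram_range[1] >= 1L, ngram_range[2] <= 3L)
  n <- length(tokens)
  grams <- character(0)
  for (k in seq(ngram_range[1], ngram_range[2])) {
    if (n >= k) {
      if (k == 1L) {
        grams <- c(grams, tokens)
      } else {
        idx <- seq_len(n - k + 1L)
        g <- tokens[idx]
        for (j in seq_len(k - 1L)) g <- paste(g, tokens[idx + j])
        grams <- c(grams, g)
      }
    }
  }
  if (length(grams) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

# Sparse accumulation of named count vectors into a dense matrix with a
# deterministic column order.
.counts_to_matrix <- function(count_list, prefix) {
  vocab <- sort(unique(unlist(lapply(count_list, names), use.names = FALSE)))
  m <- matrix(0, nrow = length(count_list), ncol = length(vocab),
              dimnames = list(NULL, if (length(vocab)) paste0(prefix, vocab)
                                    else character(0)))
  for (i in seq_along(count_list)) {
    cc <- count_list[[i]]
    if (length(cc)) m[i, paste0(prefix, names(cc))] <- as.numeric(cc)
  }
  m
}

#' Build the unit-by-feature matrix
#'
#' Assembles the enabled feature families over the analysis units: member
#' documents from [merge_by_author()] (stakeholder task) or raw messages
#' (topic task; F1 requires member documents and errors otherwise). N-gram
#' columns are pruned by document frequency, then capped by total frequency
#' with lexicographic tie-breaks. Columns are ordered family-first, then by
#' name, so the matrix is deterministic for a given corpus and spec.
#'
#' @param units Tibble of member documents (with `merged_text`) or of
#'   messages (a `forum_corpus`).
#' @param spec A [feature_spec()].
#' @param lex A `term_lexicon` (required when F3 or F4 is enabled).
#' @return A numeric matrix with `unit_ids` rownames and a `families`
#'   attribute naming each column's family.
#' @export
build_feature_matrix <- function(units, spec = feature_spec(), lex = NULL) {
  stopifnot(nrow(units) > 0L)
  is_member <- "merged_text" %in% names(units)
  if ("F1" %in% spec$families && !is_member) {
    stop("F1 style features require member documents (merge_by_author output)")
  }
  text <- if (is_member) units$merged_text else units$text
  unit_ids <- if (is_member) paste(units$forum, units$author_id, sep = "/")
              else units$message_id
  toks <- tokenize(text, simplify = FALSE)

  blocks <- list()
  fam_of <- character(0)

  if ("F1" %in% spec$families) {
    f1 <- as.matrix(extract_style_features(units))
    colnames(f1) <- paste0("f1:", colnames(f1))
    blocks$F1 <- f1
    fam_of <- c(fam_of, rep("F1", ncol(f1)))
  }
  if ("F2" %in% spec$families) {
    grams <- lapply(toks, extract_ngrams, ngram_range = spec$ngram_range)
    f2 <- .counts_to_matrix(grams, "f2:")
    if (ncol(f2) > 0L) {
      docfreq <- colSums(f2 > 0)
      f2 <- f2[, docfreq >= spec$min_doc_freq, drop = FALSE]
    }
    if (!is.null(spec$vocabulary_cap) && ncol(f2) > spec$vocabulary_cap) {
      tot <- colSums(f2)
      ord <- order(-tot, colnames(f2))
      f2 <- f2[, sort(ord[seq_len(spec$vocabulary_cap)]), drop = FALSE]
    }
    if (spec$weighting == "relative_freq" && ncol(f2) > 0L) {
      rs <- rowSums(f2)
      rs[rs == 0] <- 1
      f2 <- f2 / rs
    }
    blocks$F2 <- f2
    fam_of <- c(fam_of, rep("F2", ncol(f2)))
  }
  if ("F3" %in% spec$families) {
    if (is.null(lex)) stop("F3 requires a term lexicon")
    med <- lapply(toks, match_terms, lex = lex, category = "medical")
    f3 <- .counts_to_matrix(med, "f3:")
    blocks$F3 <- f3
    fam_of <- c(fam_of, rep("F3", ncol(f3)))
  }
  if ("F4" %in% spec$families) {
    if (is.null(lex)) stop("F4 requires a term lexicon")
    kin <- lapply(toks, match_terms, lex = lex, category = "kinship")
    f4 <- .counts_to_matrix(kin, "f4:")
    blocks$F4 <- f4
    fam_of <- c(fam_of, rep("F4", ncol(f4)))
  }

  X <- do.call(cbind, blocks)
  if (is.null(X) || ncol(X) == 0L) stop("empty feature space")
  keep <- colSums(abs(X)) > 0
  fam_of <- fam_of[keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) stop("empty feature space")
  rownames(X) <- unit_ids
  attr(X, "families") <- stats::setNames(fam_of, colnames(X))
  X
}

#' Export a feature matrix as MatrixMarket + feature-name sidecar
#'
#' Writes `<stem>.mtx` (coordinate MatrixMarket, general real) and
#' `<stem>.features.tsv` (column index, family, feature name) plus
#' `<stem>.units.tsv` (row index, unit id).
#'
#' @param X Matrix from [build_feature_matrix()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_feature_matrix <- function(X, stem) {
  idx <- which(X != 0, arr.ind = TRUE)
  con <- file(paste0(stem, ".mtx"), "w")
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(X), ncol(X), nrow(idx)), con)
  if (nrow(idx) > 0L) {
    writeLines(sprintf("%d %d %.10g", idx[, 1], idx[, 2], X[idx]), con)
  }
  close(con)
  fam <- attr(X, "families")
  utils::write.table(
    data.frame(index = seq_len(ncol(X)), family = unname(fam),
               feature = colnames(X)),
    paste0(stem, ".features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(index = seq_len(nrow(X)), unit_id = rownames(X)),
    paste0(stem, ".units.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
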
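# In-code fixtures shared across test files.

# A small corpus tibble with explicit fields.
make_corpus <- function(texts,
                        authors = paste0("a", seq_along(texts)),
                        forum = "lung_cancer",
                        days = seq_along(texts)) {
  as_corpus(tibble::tibble(
    message_id = paste0("m", seq_along(texts)),
    author_id = authors,
    forum = forum,
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + days * 86400,
    text = texts))
}

# Term lexicon file with medical and kinship entries.
make_term_lexicon_file <- function(lines = c(
                                     "pleural effusion\tmedical\tdsyn",
                                     "cough\tmedical\tsosy",
                                     "biopsy\tmedical\tdiap",
                                     "husband\tkinship\tfamg",
                                     "mother\tkinship\tfamg",
                                     "father\tkinship\tfamg",
                                     "father in law\tkinship\tfamg")) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Simplified 3-column sentiment lexicon file.
make_sentiment_file <- function(lines = c("good\t0.75\t0",
                                          "sad\t0\t0.625",
                                          "happy\t0.8\t0",
                                          "awful\t0\t0.7")) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force O(n^2) pair-counting oracle for partition metrics.
pair_count_metrics <- function(pred, ref) {
  n <- length(pred)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_p <- pred[i] == pred[j]
      same_r <- ref[i] == ref[j]
      if (same_p && same_r) a <- a + 1
      else if (!same_p && same_r) b <- b + 1
      else if (same_p && !same_r) cc <- cc + 1
      else d <- d + 1
    }
  }
  list(rand = (a + d) / (a + b + cc + d),
       jaccard = if (a + b + cc > 0) a / (a + b + cc) else 1,
       fm = if (a == 0) 0 else a / sqrt((a + b) * (a + cc)))
}

# Direct elementwise evaluation of the keyword score formula.
keyword_score_oracle <- function(F) {
  out <- matrix(0, nrow(F), ncol(F), dimnames = dimnames(F))
  N <- ncol(F)
  for (w in seq_len(nrow(F))) {
    for (i in seq_len(N)) {
      m <- sum(F[w, ] >= F[w, i])
      out[w, i] <- F[w, i] * log(N / m)
    }
  }
  out
}

pkg_term_lexicon <- function() load_term_lexicon(stakeminer_lexicon("terms"))
pkg_sentiment_lexicon <- function() {
  load_sentiment_lexicon(stakeminer_lexicon("sentiment"))
}
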
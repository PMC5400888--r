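# Term lexicons (medical / kinship, tab-separated term-category-semtype
# files) and the sentiment lexicon (SentiWordNet 3.0 layout or a simplified
# 3-column fixture). Terms are normalized with the corpus tokenizer so that
# matching is exactly consistent with feature extraction.

.semtypes <- c("sosy", "dsyn", "patf", "diap", "topp", "phsu", "lbpr", "famg")

#' Load a term lexicon (medical / kinship terminology)
#'
#' Reads a tab-separated file with columns `term`, `category`
#' (`medical` or `kinship`), `semtype` (a UMLS-style semantic-type code:
#' sosy, dsyn, patf, diap, topp, phsu, lbpr, famg). Terms are normalized
#' with [tokenize()]; multi-word terms are preserved as token sequences.
#' Duplicate (term, category) pairs collapse to one entry; rows with an
#' unknown semtype are skipped with a message.
#'
#' @param path Path to the TSV file. Lines starting with `#` are skipped.
#' @return A tibble of class `term_lexicon` with columns `term` (normalized,
#'   space-joined tokens), `n_tokens`, `category`, `semtype`.
#' @export
load_term_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    warning("empty term lexicon: ", path)
    out <- tibble::tibble(term = character(), n_tokens = integer(),
                          category = character(), semtype = character())
    class(out) <- c("term_lexicon", class(out))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok_shape <- vapply(parts, length, 1L) >= 3L
  parts <- parts[ok_shape]
  term_raw <- vapply(parts, `[[`, character(1L), 1L)
  category <- tolower(trimws(vapply(parts, `[[`, character(1L), 2L)))
  semtype <- tolower(trimws(vapply(parts, `[[`, character(1L), 3L)))
  bad <- !(semtype %in% .semtypes) | !(category %in% c("medical", "kinship"))
  if (any(bad)) {
    message(sprintf("load_term_lexicon: skipped %d line(s) with bad category/semtype",
                    sum(bad)))
  }
  toks <- tokenize(term_raw[!bad], simplify = FALSE)
  term <- vapply(toks, paste, character(1L), collapse = " ")
  out <- tibble::tibble(term = term,
                        n_tokens = vapply(toks, length, 1L),
                        category = category[!bad],
                        semtype = semtype[!bad])
  out <- out[nzchar(out$term), , drop = FALSE]
  out <- out[!duplicated(out[, c("term", "category")]), , drop = FALSE]
  out <- out[order(out$term), , drop = FALSE]
  class(out) <- c("term_lexicon", class(out))
  out
}

#' Load a sentiment lexicon
#'
#' Accepts the SentiWordNet 3.0 native layout (six tab-separated columns:
#' POS, synset id, PosScore, NegScore, `term#rank` list, gloss; `#` comment
#' lines skipped) or a simplified 3-column fixture (`term`, `pos`, `neg`).
#' Scores of a term's multiple senses are aggregated with the chosen rule;
#' the default `rank_weighted` rule is the SentiWordNet convention
#' sum(score/rank) / sum(1/rank). Aggregated positive and negative scores
#' are each capped at 1. Lookup is case-insensitive (everything is
#' lowercased on load).
#'
#' @param path Lexicon file path.
#' @param aggregation One of `"rank_weighted"` (default), `"mean"`,
#'   `"first_sense"`.
#' @return An object of class `sentiment_lexicon`: an environment-backed
#'   lookup table plus a `terms` tibble (`term`, `pos`, `neg`).
#' @export
load_sentiment_lexicon <- function(path,
                                   aggregation = c("rank_weighted", "mean",
                                                   "first_sense")) {
  aggregation <- match.arg(aggregation)
  if (!file.exists(path)) stop("sentiment lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  senses <- list()
  n_bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L && grepl("#", f[5L], fixed = TRUE)) {
      # SentiWordNet 3.0 row: POS, id, PosScore, NegScore, SynsetTerms, gloss
      pos <- suppressWarnings(as.numeric(f[3L]))
      neg <- suppressWarnings(as.numeric(f[4L]))
      if (is.na(pos) || is.na(neg)) { n_bad <- n_bad + 1L; next }
      for (entry in strsplit(f[5L], " +")[[1L]]) {
        m <- regmatches(entry, regexec("^(.*)#([0-9]+)$", entry))[[1L]]
        if (length(m) != 3L) { n_bad <- n_bad + 1L; next }
        term <- tolower(gsub("_", " ", m[2L], fixed = TRUE))
        senses[[length(senses) + 1L]] <- list(term = term,
                                              rank = as.integer(m[3L]),
                                              pos = pos, neg = neg)
      }
    } else if (length(f) >= 3L) {
      # simplified fixture: term, pos, neg (single sense, rank 1)
      pos <- suppressWarnings(as.numeric(f[2L]))
      neg <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(pos) || is.na(neg)) { n_bad <- n_bad + 1L; next }
      senses[[length(senses) + 1L]] <- list(term = tolower(trimws(f[1L])),
                                            rank = 1L, pos = pos, neg = neg)
    } else {
      n_bad <- n_bad + 1L
    }
  }
  if (n_bad > 0L) {
    message(sprintf("load_sentiment_lexicon: skipped %d malformed entr(ies)", n_bad))
  }
  df <- dplyr::bind_rows(lapply(senses, tibble::as_tibble))
  if (nrow(df) == 0L) {
    df <- tibble::tibble(term = character(), rank = integer(),
                         pos = numeric(), neg = numeric())
  }
  agg_fun <- switch(aggregation,
    rank_weighted = function(score, rank) sum(score / rank) / sum(1 / rank),
    mean = function(score, rank) mean(score),
    first_sense = function(score, rank) score[which.min(rank)]
  )
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$term),
    pos = min(1, agg_fun(.data$pos, .data$rank)),
    neg = min(1, agg_fun(.data$neg, .data$rank)),
    .groups = "drop"
  )
  tab <- new.env(parent = emptyenv(), size = max(1L, nrow(agg)))
  for (i in seq_len(nrow(agg))) {
    assign(agg$term[i], c(pos = agg$pos[i], neg = agg$neg[i]), envir = tab)
  }
  structure(list(table = tab, terms = agg, aggregation = aggregation),
            class = "sentiment_lexicon")
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat(sprintf("<sentiment_lexicon> %d terms (aggregation: %s)\n",
              nrow(x$terms), x$aggregation))
  invisible(x)
}

#' Look up sentiment scores for tokens
#'
#' @param tokens Character vector of normalized tokens.
#' @param lex A `sentiment_lexicon`.
#' @return A two-column matrix (`pos`, `neg`), one row per token; absent
#'   tokens score (0, 0).
#' @export
sentiment_lookup <- function(tokens, lex) {
  stopifnot(inherits(lex, "sentiment_lexicon"))
  out <- matrix(0, nrow = length(tokens), ncol = 2L,
                dimnames = list(NULL, c("pos", "neg")))
  for (i in seq_along(tokens)) {
    v <- get0(tokens[i], envir = lex$table, inherits = FALSE)
    if (!is.null(v)) out[i, ] <- v
  }
  out
}

#' Match lexicon terminology in a token sequence
#'
#' Greedy longest-match scan left to right: at each position the longest
#' lexicon term (up to the lexicon's maximum token length) starting there is
#' matched and its span consumed, so shorter terms never re-use a matched
#' span ("father in law" beats "father"). Matching is deterministic and
#' independent of lexicon file order.
#'
#' @param tokens Character vector of normalized tokens.
#' @param lex A `term_lexicon`.
#' @param category `"medical"` or `"kinship"`.
#' @return Named integer vector of counts per matched lexicon term (empty
#'   when nothing matches).
#' @export
match_terms <- function(tokens, lex, category = c("medical", "kinship")) {
  category <- match.arg(category)
  entries <- lex[lex$category == category, , drop = FALSE]
  if (nrow(entries) == 0L || length(tokens) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  term_set <- new.env(parent = emptyenv(), size = nrow(entries))
  for (t in entries$term) assign(t, TRUE, envir = term_set)
  max_len <- max(entries$n_tokens)
  counts <- new.env(parent = emptyenv())
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (!is.null(get0(cand, envir = term_set, inherits = FALSE))) {
        prev <- get0(cand, envir = counts, inherits = FALSE)
        assign(cand, if (is.null(prev)) 1L else prev + 1L, envir = counts)
        matched <- len
        break
      }
    }
    i <- i + max(1L, matched)
  }
  nm <- sort(ls(counts))
  stats::setNames(vapply(nm, get, 1L, envir = counts), nm)
}
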
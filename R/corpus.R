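# Corpus data model: a forum corpus is a tibble with one row per message and
# columns message_id, author_id, forum, timestamp (POSIXct, UTC), text.
# Readers, writers, preprocessing, author-level merging and the
# informational/emotional partition all operate on this shape.

.corpus_cols <- c("message_id", "author_id", "forum", "timestamp", "text")

#' Construct a forum corpus tibble
#'
#' Validates and orders a set of messages into the canonical corpus layout:
#' one row per message, ordered by timestamp within forum, timestamps stored
#' timezone-naive UTC.
#'
#' @param messages Data frame with columns `message_id`, `author_id`,
#'   `forum`, `timestamp` (POSIXct or ISO-8601 strings), `text`.
#' @param provenance Optional list recording how the corpus was produced
#'   (config, seed); stored as the `provenance` attribute.
#' @return A tibble of class `forum_corpus`.
#' @export
as_corpus <- function(messages, provenance = NULL) {
  stopifnot(is.data.frame(messages))
  missing_cols <- setdiff(.corpus_cols, names(messages))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(messages)[, .corpus_cols]
  if (!inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%d"))
  }
  attr(out$timestamp, "tzone") <- "UTC"
  for (col in c("message_id", "author_id", "forum", "text")) {
    out[[col]] <- as.character(out[[col]])
  }
  dup <- duplicated(out[, c("forum", "message_id")])
  if (any(dup)) stop("duplicate (forum, message_id) pairs in corpus")
  out <- out[order(out$forum, out$timestamp, out$message_id), , drop = FALSE]
  attr(out, "provenance") <- provenance
  class(out) <- c("forum_corpus", class(out))
  out
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat(sprintf("<forum_corpus> %d messages, %d authors, %d forum(s)\n",
              nrow(x), length(unique(x$author_id)), length(unique(x$forum))))
  NextMethod()
}

#' Read a forum corpus from JSONL or CSV
#'
#' Each record must carry the five message fields (`message_id`, `author_id`,
#' `forum`, `timestamp` as ISO-8601, `text`). Records with a missing or empty
#' mandatory field are dropped and counted; the load report is attached as
#' the `load_report` attribute and surfaced as a message.
#'
#' @param path File path.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`. Guessed
#'   from the file extension when omitted.
#' @return A `forum_corpus` tibble with a `load_report` attribute:
#'   `list(n_read, n_kept, n_dropped)`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(ln) {
      tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    })
    bad_json <- vapply(recs, is.null, logical(1L))
    recs <- recs[!bad_json]
    df <- if (length(recs) == 0L) {
      tibble::tibble(message_id = character(), author_id = character(),
                     forum = character(), timestamp = character(),
                     text = character())
    } else {
      dplyr::bind_rows(lapply(recs, function(r) {
        r <- r[intersect(names(r), .corpus_cols)]
        tibble::as_tibble(lapply(r, function(v) as.character(v)[1L]))
      }))
    }
    n_read <- length(lines)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    n_read <- nrow(df)
    bad_json <- logical(0L)
  }
  for (col in .corpus_cols) if (is.null(df[[col]])) df[[col]] <- NA_character_
  ok <- rep(TRUE, nrow(df))
  for (col in .corpus_cols) {
    ok <- ok & !is.na(df[[col]]) & nzchar(trimws(df[[col]]))
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"), optional = TRUE)
  ok <- ok & !is.na(ts)
  kept <- df[ok, .corpus_cols, drop = FALSE]
  report <- list(n_read = n_read,
                 n_kept = nrow(kept),
                 n_dropped = n_read - nrow(kept))
  if (report$n_dropped > 0L) {
    message(sprintf("read_corpus: dropped %d of %d records (missing/empty fields)",
                    report$n_dropped, n_read))
  }
  out <- as_corpus(kept)
  attr(out, "load_report") <- report
  out
}

#' Write a forum corpus to JSONL or CSV
#'
#' @param corpus A `forum_corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- as.data.frame(corpus)[, .corpus_cols]
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]), auto_unbox = TRUE)
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Preprocess a corpus
#'
#' Normalizes and filters messages: every retained message has at least
#' `min_tokens` word tokens after tokenization (lowercasing, URL/markup
#' stripping), and exact duplicate (author, text) pairs are collapsed to the
#' earliest timestamp. Raw text is kept; all downstream comparisons go
#' through [tokenize()] and are therefore case-insensitive.
#'
#' @param corpus A `forum_corpus`.
#' @param min_tokens Minimum word-token count per message (default 1).
#' @param dedupe Collapse exact `(author_id, text)` duplicates (default TRUE);
#'   duplicate texts are compared case-insensitively on the token sequence.
#' @return Filtered `forum_corpus`; a `preprocess_report` attribute counts
#'   drops by reason. Warns when the result is empty.
#' @export
preprocess <- function(corpus, min_tokens = 1L, dedupe = TRUE) {
  toks <- tokenize(corpus$text, simplify = FALSE)
  n_tok <- vapply(toks, length, 1L)
  keep <- n_tok >= min_tokens
  n_short <- sum(!keep)
  out <- corpus[keep, , drop = FALSE]
  n_dup <- 0L
  if (dedupe && nrow(out) > 0L) {
    key <- paste(out$author_id,
                 vapply(tokenize(out$text, simplify = FALSE),
                        paste, character(1L), collapse = " "),
                 sep = "\r")
    ord <- order(out$timestamp)
    first <- !duplicated(key[ord])
    keep2 <- logical(nrow(out))
    keep2[ord] <- first
    n_dup <- sum(!keep2)
    out <- out[keep2, , drop = FALSE]
  }
  out <- out[order(out$forum, out$timestamp, out$message_id), , drop = FALSE]
  if (nrow(out) == 0L) warning("preprocess: corpus is empty after filtering")
  attr(out, "preprocess_report") <- list(n_in = nrow(corpus),
                                         n_dropped_short = n_short,
                                         n_dropped_duplicate = n_dup,
                                         n_out = nrow(out))
  attr(out, "provenance") <- attr(corpus, "provenance")
  class(out) <- unique(c("forum_corpus", class(out)))
  out
}

#' Merge all of an author's messages into one member document
#'
#' One row per (author, forum): the author's messages concatenated in
#' first-posted order, plus the style statistics the clustering uses —
#' message count, sentence count (terminal-punctuation splitting, see
#' [count_sentences()]), and word-token count.
#'
#' @param corpus A preprocessed `forum_corpus`.
#' @return Tibble with columns `author_id`, `forum`, `merged_text`,
#'   `message_count`, `sentence_count`, `word_count`.
#' @export
merge_by_author <- function(corpus) {
  stopifnot(nrow(corpus) > 0L)
  df <- as.data.frame(corpus)
  df <- df[order(df$forum, df$author_id, df$timestamp, df$message_id), ]
  df$n_sent <- count_sentences(df$text)
  df$n_word <- vapply(tokenize(df$text, simplify = FALSE), length, 1L)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$author_id, .data$forum),
    merged_text = paste(.data$text, collapse = " "),
    message_count = dplyr::n(),
    sentence_count = sum(.data$n_sent),
    word_count = sum(.data$n_word),
    first_post = min(.data$timestamp),
    .groups = "drop"
  )
  out[order(out$forum, out$author_id), , drop = FALSE]
}

#' Partition a corpus into informational and emotional messages
#'
#' A message is *emotional* when its subjective polarity sum (positive +
#' negative sentiment-lexicon scores of its tokens, see [score_message()])
#' is at least `tau`; otherwise it is *informational*. The two outputs
#' partition the input exactly.
#'
#' @param corpus A `forum_corpus`.
#' @param lex A sentiment lexicon from [load_sentiment_lexicon()].
#' @param tau Subjectivity threshold (default 1.0); must be >= 0.
#' @return `list(informational = , emotional = )` of `forum_corpus` tibbles.
#' @export
filter_informational <- function(corpus, lex, tau = 1.0) {
  stopifnot(tau >= 0)
  subj <- if (nrow(corpus) == 0L) numeric(0) else {
    sc <- score_corpus(corpus, lex)
    sc$subjective_sum
  }
  emo <- subj >= tau
  list(informational = corpus[!emo, , drop = FALSE],
       emotional = corpus[emo, , drop = FALSE])
}
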
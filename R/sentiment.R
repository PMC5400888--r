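# Lexicon-based sentiment measurement. Every token occurrence found in the
# sentiment lexicon contributes its aggregated (positive, negative) scores
# to the message's sums; the subjective sum is exactly positive + negative.
# Group-level measures are per-message means of the sums:
#   PositiveScores  = sum(pos_sum)  / n_messages
#   NegativeScores  = sum(neg_sum)  / n_messages
#   SubjectiveScores = sum(subjective_sum) / n_messages

#' Sentiment sums of one token sequence
#'
#' @param tokens Character vector of normalized tokens.
#' @param lex A `sentiment_lexicon`.
#' @return List with `pos_sum`, `neg_sum`, `subjective_sum`.
#' @export
score_message <- function(tokens, lex) {
  sc <- sentiment_lookup(tokens, lex)
  pos <- sum(sc[, "pos"])
  neg <- sum(sc[, "neg"])
  list(pos_sum = pos, neg_sum = neg, subjective_sum = pos + neg)
}

#' Sentiment sums for every message of a corpus
#'
#' @param corpus A `forum_corpus`.
#' @param lex A `sentiment_lexicon`.
#' @return Tibble with `message_id`, `pos_sum`, `neg_sum`, `subjective_sum`,
#'   aligned with the corpus rows.
#' @export
score_corpus <- function(corpus, lex) {
  toks <- tokenize(corpus$text, simplify = FALSE)
  pos <- neg <- numeric(nrow(corpus))
  for (i in seq_along(toks)) {
    sc <- sentiment_lookup(toks[[i]], lex)
    pos[i] <- sum(sc[, "pos"])
    neg[i] <- sum(sc[, "neg"])
  }
  tibble::tibble(message_id = corpus$message_id,
                 pos_sum = pos, neg_sum = neg,
                 subjective_sum = pos + neg)
}

#' Group-level sentiment measures
#'
#' Pools the messages of each group and reports the three per-message means:
#' PositiveScores, NegativeScores, SubjectiveScores. Empty groups are
#' omitted (they have no message denominator).
#'
#' @param scored Tibble from [score_corpus()] (or any tibble with `pos_sum`,
#'   `neg_sum`, `subjective_sum`).
#' @param group Vector of group keys, one per row of `scored`.
#' @return Tibble with `group`, `n_messages`, `positive_scores`,
#'   `negative_scores`, `subjective_scores`.
#' @export
sentiment_measures <- function(scored, group) {
  stopifnot(nrow(scored) == length(group))
  df <- tibble::tibble(group = group,
                       pos_sum = scored$pos_sum,
                       neg_sum = scored$neg_sum,
                       subjective_sum = scored$subjective_sum)
  dplyr::summarise(
    dplyr::group_by(df, .data$group),
    n_messages = dplyr::n(),
    positive_scores = sum(.data$pos_sum) / dplyr::n(),
    negative_scores = sum(.data$neg_sum) / dplyr::n(),
    subjective_scores = sum(.data$subjective_sum) / dplyr::n(),
    .groups = "drop"
  )
}

#' Classify message polarity
#'
#' Positive when the positive sum exceeds the negative sum, negative for the
#' reverse, neutral on ties (including the all-zero message). Neutral
#' messages are excluded from positive/negative share denominators.
#'
#' @param scored Tibble with `pos_sum` and `neg_sum`.
#' @return Character vector: `"positive"`, `"negative"`, or `"neutral"`.
#' @export
classify_polarity <- function(scored) {
  ifelse(scored$pos_sum > scored$neg_sum, "positive",
         ifelse(scored$neg_sum > scored$pos_sum, "negative", "neutral"))
}

#' Half-month sentiment trend series per group
#'
#' Time origin is each author's first post; a message posted `d` days later
#' falls in bin `floor(d / 15)` (half-open 15-day bins), and messages from
#' day 360 onward (bin >= 24) are dropped, covering exactly the author's
#' first year. Within each group and bin the three sentiment measures are
#' computed over the pooled messages.
#'
#' @param corpus A `forum_corpus`.
#' @param scored Tibble from [score_corpus()], aligned with `corpus`.
#' @param group Vector of group keys, one per message.
#' @param n_bins Number of 15-day bins to keep (default 24, one year).
#' @return Tibble with `group`, `bin` (0-based), `n_messages` and the three
#'   measures; only observed (group, bin) cells are present.
#' @export
trend_series <- function(corpus, scored, group, n_bins = 24L) {
  stopifnot(nrow(corpus) == nrow(scored), nrow(corpus) == length(group))
  df <- tibble::tibble(author_id = corpus$author_id,
                       timestamp = corpus$timestamp,
                       group = group,
                       pos_sum = scored$pos_sum,
                       neg_sum = scored$neg_sum,
                       subjective_sum = scored$subjective_sum)
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$author_id),
    days = as.numeric(difftime(.data$timestamp, min(.data$timestamp),
                               units = "days")))
  df <- dplyr::ungroup(df)
  df$bin <- floor(df$days / 15)
  df <- df[df$bin < n_bins, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$bin),
    n_messages = dplyr::n(),
    positive_scores = sum(.data$pos_sum) / dplyr::n(),
    negative_scores = sum(.data$neg_sum) / dplyr::n(),
    subjective_scores = sum(.data$subjective_sum) / dplyr::n(),
    .groups = "drop"
  )
  out$bin <- as.integer(out$bin)
  out[order(out$group, out$bin), , drop = FALSE]
}
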
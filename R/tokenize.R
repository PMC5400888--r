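# Text normalization primitives shared by every module. All word counts,
# n-grams, lexicon matches and sentiment lookups are defined over exactly
# this tokenization, so it lives in one place.

#' Tokenize text into normalized word tokens
#'
#' Lowercases, strips URLs and HTML-like markup, then extracts word tokens as
#' maximal runs of Unicode letters, digits, and apostrophes. Tokens consisting
#' only of apostrophes are discarded. This single tokenizer underlies all
#' word counts, n-gram features, terminology matching, and sentiment lookup,
#' so counts are consistent across the pipeline.
#'
#' @param text Character vector of raw message texts.
#' @return A list of character vectors, one per input element (a single
#'   character vector if `text` has length 1 and `simplify = TRUE`).
#' @param simplify If `TRUE` (default) and `text` has length 1, return the
#'   bare token vector instead of a one-element list.
#' @examples
#' tokenize("My husband's CT scan -- see http://example.com!")
#' @export
tokenize <- function(text, simplify = TRUE) {
  cleaned <- tolower(text)
  cleaned <- gsub("https?://\\S+|www\\.\\S+", " ", cleaned, perl = TRUE)
  cleaned <- gsub("<[^>]*>", " ", cleaned, perl = TRUE)
  toks <- regmatches(cleaned, gregexpr("[\\p{L}\\p{N}']+", cleaned, perl = TRUE))
  toks <- lapply(toks, function(tk) tk[!grepl("^'+$", tk)])
  if (simplify && length(toks) == 1L) toks[[1L]] else toks
}

# Abbreviations whose trailing period must not end a sentence.
.abbreviations <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "vs", "etc", "e.g", "i.e",
  "approx", "dept", "jan", "feb", "mar", "apr", "jun", "jul", "aug",
  "sep", "oct", "nov", "dec"
)

#' Count sentences in a message
#'
#' Splits on terminal punctuation (`.`, `!`, `?`), ignoring periods that
#' terminate a known abbreviation. A segment counts as a sentence only if it
#' contains at least one word token; a message with word tokens but no
#' terminal punctuation counts as one sentence.
#'
#' @param text Character vector of message texts.
#' @return Integer vector of sentence counts (0 only for messages with no
#'   word tokens at all).
#' @export
count_sentences <- function(text) {
  vapply(text, function(x) {
    # Shield abbreviation periods, then split on runs of terminal punctuation.
    low <- tolower(x)
    for (ab in .abbreviations) {
      low <- gsub(paste0("\\b", gsub(".", "\\.", ab, fixed = TRUE), "\\."),
                  ab, low, perl = TRUE)
    }
    segs <- strsplit(low, "[.!?]+", perl = TRUE)[[1L]]
    n <- sum(vapply(tokenize(segs, simplify = FALSE), length, 1L) > 0L)
    if (n == 0L && length(tokenize(x)) > 0L) n <- 1L
    as.integer(n)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Default English stopword list
#'
#' A compact list of English function words used when filtering cluster
#' keywords. An n-gram is suppressed only when *all* of its tokens are
#' stopwords, so content-bearing multi-word phrases such as "thank you"
#' survive the filter.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "the", "and", "or", "but", "if", "then", "than", "so",
    "of", "in", "on", "at", "to", "for", "from", "by", "with", "about",
    "as", "into", "over", "after", "before", "between", "out", "up",
    "down", "off", "is", "am", "are", "was", "were", "be", "been",
    "being", "do", "does", "did", "doing", "have", "has", "had",
    "having", "will", "would", "can", "could", "shall", "should", "may",
    "might", "must", "i", "me", "my", "mine", "we", "us", "our", "ours",
    "you", "your", "yours", "he", "him", "his", "she", "her", "hers",
    "it", "its", "they", "them", "their", "theirs", "this", "that",
    "these", "those", "there", "here", "what", "which", "who", "whom",
    "when", "where", "why", "how", "not", "no", "nor", "very", "too",
    "just", "also", "only", "own", "same", "some", "any", "all", "each",
    "both", "more", "most", "other", "such", "s", "t", "don't", "its",
    "i'm", "i've", "it's"
  )
}
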
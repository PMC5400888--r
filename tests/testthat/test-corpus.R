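test_that("JSONL corpora load, drop invalid records, and round-trip", {
  corpus <- make_corpus(c("i have a cough", "my husband is ill",
                          "you should rest"))
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(nrow(back), 3L)
  expect_equal(attr(back, "load_report")$n_dropped, 0L)
  expect_equal(as.data.frame(back), as.data.frame(corpus), ignore_attr = TRUE)

  # a record with empty text is dropped and counted
  lines <- readLines(path)
  bad <- sub("\"text\":\"[^\"]*\"", "\"text\":\"\"", lines[2])
  bad <- sub("\"message_id\":\"m2\"", "\"message_id\":\"mX\"", bad)
  writeLines(c(lines, bad), path)
  suppressMessages(back2 <- read_corpus(path))
  expect_equal(nrow(back2), 3L)
  expect_equal(attr(back2, "load_report")$n_dropped, 1L)

  # CSV round-trip carries the same fields
  csv <- tempfile(fileext = ".csv")
  write_corpus(corpus, csv)
  expect_equal(as.data.frame(read_corpus(csv)), as.data.frame(corpus), ignore_attr = TRUE)

  expect_error(read_corpus(tempfile()), "not found")
})

test_that("preprocess enforces token minimum and collapses duplicates", {
  corpus <- make_corpus(
    c("!!!", "Hello there", "hello THERE", "something else"),
    authors = c("a1", "a2", "a2", "a2"))
  out <- preprocess(corpus, min_tokens = 1)
  rep <- attr(out, "preprocess_report")
  expect_equal(rep$n_dropped_short, 1L)        # "!!!" has no word tokens
  expect_equal(rep$n_dropped_duplicate, 1L)    # case-insensitive dup by a2
  expect_equal(nrow(out), 2L)
  # earliest duplicate retained
  expect_true("Hello there" %in% out$text)
  expect_false("hello THERE" %in% out$text)
  expect_warning(preprocess(make_corpus("???")), "empty")
})

test_that("merge_by_author aggregates counts and style statistics", {
  corpus <- make_corpus(c("I cough. Often.", "Help me"),
                        authors = c("a1", "a1"))
  doc <- merge_by_author(corpus)
  expect_equal(nrow(doc), 1L)
  expect_equal(doc$message_count, 2L)
  expect_equal(doc$sentence_count, 3L)
  expect_equal(doc$sentence_count / doc$message_count, 1.5)
  expect_equal(doc$merged_text, "I cough. Often. Help me")

  single <- merge_by_author(make_corpus("one message"))
  expect_equal(single$message_count, 1L)

  # total message count conserved per forum
  corpus2 <- make_corpus(letters[1:6],
                         authors = c("a", "a", "b", "c", "c", "c"),
                         forum = rep(c("f1", "f2"), each = 3))
  docs <- merge_by_author(corpus2)
  expect_equal(sum(docs$message_count[docs$forum == "f1"]), 3L)
  expect_equal(sum(docs$message_count[docs$forum == "f2"]), 3L)
})

test_that("sentence counting splits on terminal punctuation, keeps abbreviations", {
  expect_equal(count_sentences("I cough. Often."), 2L)
  expect_equal(count_sentences("no punctuation at all"), 1L)
  expect_equal(count_sentences("Dr. Smith saw me. It helped!"), 2L)
  expect_equal(count_sentences("Really?! Yes. Ok."), 3L)
  expect_equal(count_sentences("..."), 0L)
})

test_that("informational/emotional split partitions the corpus at any threshold", {
  lex <- load_sentiment_lexicon(make_sentiment_file())
  # 3 messages constructed with subjective sum >= 1, 7 below
  texts <- c(rep("plain facts here", 5),
             "good result overall", "slightly sad news",
             "good good news", "sad and awful day", "happy happy day")
  corpus <- make_corpus(texts)
  split <- filter_informational(corpus, lex, tau = 1.0)
  expect_equal(nrow(split$informational), 7L)
  expect_equal(nrow(split$emotional), 3L)

  # tau = 0: any message (even without sentiment terms) has sum >= 0
  split0 <- filter_informational(corpus, lex, tau = 0)
  expect_equal(nrow(split0$emotional), nrow(corpus))

  # message with no lexicon terms is informational for any tau > 0
  lone <- filter_informational(make_corpus("plain facts"), lex, tau = 1e-9)
  expect_equal(nrow(lone$informational), 1L)

  # partition property and monotonicity over a tau grid
  prev_emotional <- Inf
  for (tau in c(0, 0.5, 0.625, 1, 1.5, 10)) {
    s <- filter_informational(corpus, lex, tau = tau)
    expect_equal(nrow(s$informational) + nrow(s$emotional), nrow(corpus))
    expect_lte(nrow(s$emotional), prev_emotional)
    prev_emotional <- nrow(s$emotional)
  }
})

test_that("tokenization lowercases, strips urls/markup, keeps apostrophes", {
  expect_equal(tokenize("My husband's CT scan -- see http://x.io/a!"),
               c("my", "husband's", "ct", "scan", "see"))
  expect_equal(tokenize("<b>bold</b> text"), c("bold", "text"))
  expect_equal(tokenize("''' ..."), character(0))
})
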
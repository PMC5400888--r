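test_that("style features are the three per-member statistics", {
  doc <- tibble::tibble(message_count = 4L, sentence_count = 10L,
                        word_count = 60L)
  f <- extract_style_features(doc)
  expect_equal(unlist(f), c(message_count = 4,
                            avg_sentences_per_message = 2.5,
                            words_per_message = 15))
  one <- extract_style_features(tibble::tibble(message_count = 1L,
                                               sentence_count = 1L,
                                               word_count = 1L))
  expect_equal(unname(unlist(one)), c(1, 1, 1))
})

test_that("n-gram extraction enumerates contiguous word n-grams", {
  g <- extract_ngrams(c("my", "left", "lung"), c(1, 3))
  expect_length(g, 6L)
  expect_true(all(g == 1L))
  expect_setequal(names(g), c("my", "left", "lung", "my left", "left lung",
                              "my left lung"))
  expect_equal(extract_ngrams(c("a", "a", "a"), c(1, 1)), c(a = 3L))
  expect_length(extract_ngrams(character(0), c(1, 3)), 0L)
})

test_that("feature matrices assemble, prune, and order deterministically", {
  corpus <- make_corpus(
    c("i have a cough today", "i have a cough again", "i have a cough still",
      "my husband has pleural effusion", "you should see your doctor"),
    authors = paste0("a", 1:5))
  docs <- merge_by_author(corpus)
  lex <- load_term_lexicon(make_term_lexicon_file())

  # F1 only: exactly the three style columns
  X1 <- build_feature_matrix(docs, feature_spec(families = "F1"))
  expect_equal(dim(X1), c(5L, 3L))
  expect_equal(unname(attr(X1, "families")), rep("F1", 3))

  # min_doc_freq prunes n-grams present in fewer units
  X2 <- build_feature_matrix(docs, feature_spec(families = "F2",
                                                min_doc_freq = 3))
  expect_true("f2:cough" %in% colnames(X2))
  expect_false("f2:husband" %in% colnames(X2))

  # determinism: identical output on repeated calls
  spec <- feature_spec(min_doc_freq = 1)
  Xa <- build_feature_matrix(docs, spec, lex = lex)
  Xb <- build_feature_matrix(docs, spec, lex = lex)
  expect_identical(Xa, Xb)

  # adding families never removes columns
  fams <- list("F1", c("F1", "F2"), c("F1", "F2", "F3"),
               c("F1", "F2", "F3", "F4"))
  prev <- character(0)
  for (fm in fams) {
    X <- build_feature_matrix(docs, feature_spec(families = fm,
                                                 min_doc_freq = 1),
                              lex = lex)
    expect_true(all(prev %in% colnames(X)))
    prev <- colnames(X)
  }

  # relative_freq weighting: each unit's F2 block sums to 1
  Xr <- build_feature_matrix(docs, feature_spec(families = "F2",
                                                min_doc_freq = 1,
                                                weighting = "relative_freq"))
  expect_equal(unname(rowSums(Xr)), rep(1, 5))

  # vocabulary cap keeps the most frequent n-grams
  Xc <- build_feature_matrix(docs, feature_spec(families = "F2",
                                                min_doc_freq = 1,
                                                vocabulary_cap = 3))
  expect_equal(ncol(Xc), 3L)

  # no all-zero columns survive; empty feature space errors
  expect_true(all(colSums(abs(Xa)) > 0))
  expect_error(build_feature_matrix(docs, feature_spec(families = "F2",
                                                       min_doc_freq = 99)),
               "empty feature space")
})

test_that("feature matrices export as MatrixMarket with sidecars", {
  docs <- merge_by_author(make_corpus(c("a b c", "a b", "a")))
  X <- build_feature_matrix(docs, feature_spec(families = "F2",
                                               min_doc_freq = 1))
  stem <- tempfile()
  write_feature_matrix(X, stem)
  header <- readLines(paste0(stem, ".mtx"), n = 2)
  expect_match(header[1], "MatrixMarket")
  dims <- as.integer(strsplit(header[2], " ")[[1]])
  expect_equal(dims[1:2], dim(X))
  feats <- read.delim(paste0(stem, ".features.tsv"))
  expect_equal(nrow(feats), ncol(X))
})
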
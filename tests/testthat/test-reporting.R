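test_that("descriptive statistics reproduce messages-per-member ratios", {
  # forum shaped like a large community: 5317 messages over 2416 members
  n_members <- 2416L
  n_messages <- 5317L
  authors <- c(paste0("a", seq_len(n_members)),
               paste0("a", sample.int(n_members, n_messages - n_members,
                                      replace = TRUE)))
  corpus <- as_corpus(tibble::tibble(
    message_id = paste0("m", seq_len(n_messages)),
    author_id = authors,
    forum = "lung_cancer",
    timestamp = as.POSIXct("2010-01-01", tz = "UTC") + seq_len(n_messages),
    text = "t"))
  st <- descriptive_stats(corpus)
  expect_equal(st$n_messages, 5317L)
  expect_equal(st$n_members, 2416L)
  expect_equal(st$messages_per_member_2dp, 2.20)

  single <- descriptive_stats(make_corpus("only one"))
  expect_equal(single$messages_per_member_2dp, 1.00)
})

test_that("half-up rounding matches table presentation conventions", {
  expect_equal(round_half_up(2.195, 2), 2.20)
  expect_equal(round_half_up(2.204999, 2), 2.20)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("crosstabs carry auditable numerators and denominators", {
  rows <- c(rep("patient", 1657))
  cols <- c(rep("symptom", 536), rep("other", 1657 - 536))
  ct <- crosstab(rows, cols)
  sym <- ct[ct$col == "symptom", ]
  expect_equal(sym$n, 536L)
  expect_equal(sym$row_total, 1657L)
  expect_equal(sym$pct_2dp, 32.35)  # 536/1657 = 32.3476%, half-up
  # row sums reconstruct the denominator
  expect_equal(sum(ct$n), unique(ct$row_total))

  one <- crosstab("g", "x")
  expect_equal(one$pct_2dp, 100)

  # permuting unit order leaves all cells unchanged
  set.seed(1)
  perm <- sample(length(rows))
  expect_equal(crosstab(rows[perm], cols[perm]), ct)
  expect_error(crosstab(1:3, 1:4), "length")
})

test_that("the end-to-end pipeline runs on a tiny corpus and is reproducible", {
  g <- generate_corpus(preset("tiny", seed = 4))
  lex <- pkg_term_lexicon()
  slex <- pkg_sentiment_lexicon()
  out_dir <- tempfile()
  bundle <- run_pipeline(g$corpus, lex, slex, task = "all", k = 3,
                         seed = 11, ref_members = g$members,
                         out_dir = out_dir)
  expect_equal(bundle$stakeholder$k, 3L)
  expect_s3_class(bundle$stakeholder$keywords[[1]], "tbl_df")
  expect_true(all(c("rand", "jaccard", "fm") %in%
                  names(bundle$stakeholder$metrics)))
  expect_equal(bundle$informational_split$n_informational +
               bundle$informational_split$n_emotional, nrow(g$corpus))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_true(all(unlist(manifest$outputs) %in% list.files(out_dir)))

  # same config and seed: identical stakeholder labels
  bundle2 <- run_pipeline(g$corpus, lex, slex, task = "stakeholder", k = 3,
                          seed = 11, ref_members = g$members)
  expect_identical(bundle$stakeholder$assignment$labels,
                   bundle2$stakeholder$assignment$labels)

  # sentiment identities hold at group level in the bundle
  sm <- bundle$sentiment$measures_by_group
  expect_equal(sm$subjective_scores,
               sm$positive_scores + sm$negative_scores)
})

test_that("stakeholder keywords surface the planted group vocabulary", {
  g <- generate_corpus(preset("tiny", seed = 6))
  cp <- preprocess(g$corpus)
  mem <- merge_by_author(cp)
  gold <- g$members$group[match(mem$author_id, g$members$author_id)]
  freq <- cluster_term_frequencies(mem$merged_text, gold)
  scores <- keyword_score(freq)
  kw_caregiver <- top_keywords(scores, which(colnames(freq) == "caregiver"),
                               k = 25)
  expect_true(any(grepl("husband|mother|wife|son|daughter|mom|dad",
                        kw_caregiver$term)))
  kw_specialist <- top_keywords(scores, which(colnames(freq) == "specialist"),
                                k = 25)
  expect_true(any(grepl("you|your", kw_specialist$term)))
})
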
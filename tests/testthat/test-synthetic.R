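test_that("generation is deterministic and matches configured counts", {
  cfg <- preset("tiny", seed = 5)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$text, g2$corpus$text)
  expect_identical(g1$corpus$timestamp, g2$corpus$timestamp)
  expect_identical(g1$messages, g2$messages)

  counts <- table(g1$members$group)
  expect_equal(unname(counts[c("patient", "caregiver", "specialist")]),
               c(25L, 20L, 15L), ignore_attr = TRUE)
  # every generated unit is labeled
  expect_setequal(g1$messages$message_id, g1$corpus$message_id)
  expect_equal(nrow(g1$members), length(unique(g1$corpus$author_id)))
})

test_that("invalid generator configs fail validation with specifics", {
  expect_error(
    synth_config(topic_mixture = list(
      patient = c(symptom = 0.9, complication = 0.3, examination = 0,
                  procedure = 0, drug = 0),
      caregiver = c(symptom = 0.2, complication = 0.2, examination = 0.2,
                    procedure = 0.2, drug = 0.2),
      specialist = c(symptom = 0.2, complication = 0.2, examination = 0.2,
                     procedure = 0.2, drug = 0.2))),
    "topic_mixture")
  expect_error(synth_config(emotional_prob = c(patient = 1.4, caregiver = 0.1,
                                               specialist = 0.1)),
               "emotional_prob")
  expect_error(preset("nope"))
})

test_that("generated corpora survive IO and preprocessing with zero drops", {
  g <- generate_corpus(preset("tiny", seed = 2))
  path <- tempfile(fileext = ".jsonl")
  write_corpus(g$corpus, path)
  back <- read_corpus(path)
  expect_equal(attr(back, "load_report")$n_dropped, 0L)
  pp <- preprocess(back)
  expect_equal(nrow(pp), nrow(g$corpus))
})

test_that("generator vocabulary is covered by the packaged lexicons", {
  g <- generate_corpus(preset("tiny", seed = 3))
  lex <- pkg_term_lexicon()
  slex <- pkg_sentiment_lexicon()
  # every planted topic term and kinship term is matchable
  toks <- tokenize(paste(g$corpus$text, collapse = " "))
  med <- match_terms(toks, lex, "medical")
  kin <- match_terms(toks, lex, "kinship")
  expect_gt(sum(med), nrow(g$corpus) * 0.8)
  expect_gt(sum(kin), 0)
  # emotional messages always cross the default subjectivity threshold,
  # informational ones never do
  scored <- score_corpus(g$corpus, slex)
  emo <- g$messages$emotional[match(g$corpus$message_id,
                                    g$messages$message_id)]
  expect_true(all(scored$subjective_sum[emo] >= 1))
  expect_true(all(scored$subjective_sum[!emo] < 1))
})

test_that("paperlike preset mirrors the community's shape", {
  cfg <- preset("paperlike", seed = 1)
  lung <- cfg$forums$lung_cancer$members
  ratio <- 100 * lung / sum(lung)
  expect_lt(abs(ratio[["patient"]] - 49.75), 2)
  expect_lt(abs(ratio[["caregiver"]] - 43.58), 2)
  expect_lt(abs(ratio[["specialist"]] - 6.66), 2)

  # volume skew by construction: configured specialist posting rates are at
  # least 10x the patient rates in every forum
  for (f in cfg$forums) {
    expect_gte(f$messages_per_member[["specialist"]],
               10 * f$messages_per_member[["patient"]])
  }
  # and empirically, pooled over forums
  g <- generate_corpus(cfg)
  stats <- descriptive_stats(g$corpus, labels = g$members)
  pooled <- function(grp) {
    sel <- stats$group == grp
    sum(stats$n_messages[sel]) / sum(stats$n_members[sel])
  }
  expect_gte(pooled("specialist"), 10 * pooled("patient"))
})

test_that("per-group topic mixtures converge to the configured mixture", {
  cfg <- preset("topiclike", seed = 8)
  g <- generate_corpus(cfg)
  grp <- g$members$group[match(g$corpus$author_id, g$members$author_id)]
  topic <- g$messages$topic[match(g$corpus$message_id,
                                  g$messages$message_id)]
  for (gname in c("patient", "caregiver")) {
    obs <- table(factor(topic[grp == gname],
                        levels = names(cfg$topic_mixture[[gname]])))
    expect_gt(sum(obs), 500)
    p <- chisq.test(obs, p = cfg$topic_mixture[[gname]])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("the full pipeline recovers the planted groups on the default config", {
  g <- generate_corpus(synth_config(seed = 23))
  lex <- pkg_term_lexicon()
  cp <- preprocess(g$corpus)
  mem <- merge_by_author(cp)
  X <- build_feature_matrix(mem, feature_spec(), lex = lex)
  expect_equal(select_k(X, k_max = 6, folds = 10, seed = 23)$k, 3L)
  fit <- fit_em(X, 3, seed = 23)
  gold <- g$members$group[match(mem$author_id, g$members$author_id)]
  expect_gte(partition_metrics(fit$assignment$labels, gold)$rand, 0.9)
})

test_that("the planted emotional fraction is recovered by the threshold split", {
  cfg <- preset("topiclike", seed = 13)
  g <- generate_corpus(cfg)
  slex <- pkg_sentiment_lexicon()
  split <- filter_informational(g$corpus, slex, tau = 1.0)
  planted <- mean(g$messages$emotional)
  recovered <- nrow(split$emotional) / nrow(g$corpus)
  expect_lt(abs(recovered - planted), 0.03)
})
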
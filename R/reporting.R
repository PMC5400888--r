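# Descriptive statistics, cross-tabulations, and the end-to-end pipeline
# runner tying the three analyses (stakeholder, topic, sentiment) together.

#' Per-forum (and per-group) corpus descriptive statistics
#'
#' Message counts, member counts, and messages per member, the latter
#' reported both at full precision and rounded half-up to 2 decimal places
#' (presentation convention for all ratios in this package).
#'
#' @param corpus A `forum_corpus`.
#' @param labels Optional tibble (`author_id`, `forum`, `group`) of member
#'   group labels; when given, statistics are additionally broken down by
#'   group within forum.
#' @return Tibble with `forum` (and `group` when labelled), `n_messages`,
#'   `n_members`, `messages_per_member`, `messages_per_member_2dp`.
#' @export
descriptive_stats <- function(corpus, labels = NULL) {
  stopifnot(nrow(corpus) > 0L)
  df <- tibble::tibble(forum = corpus$forum, author_id = corpus$author_id)
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("author_id", "forum", "group")],
                           by = c("forum", "author_id"))
    grp <- dplyr::group_by(df, .data$forum, .data$group)
  } else {
    grp <- dplyr::group_by(df, .data$forum)
  }
  out <- dplyr::summarise(
    grp,
    n_messages = dplyr::n(),
    n_members = dplyr::n_distinct(.data$author_id),
    .groups = "drop")
  out$messages_per_member <- out$n_messages / out$n_members
  out$messages_per_member_2dp <- round_half_up(out$messages_per_member, 2L)
  out
}

#' Round half away from zero
#'
#' Fixed-precision presentation rounding (2.345 -> 2.35 at 2 d.p.), unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # epsilon guards against binary representation of decimal halves
  # (2.195 * 100 is fractionally below 219.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Cross-tabulate two label vectors with auditable proportions
#'
#' Counts per (row, column) cell with row denominators, so every reported
#' proportion carries its numerator/denominator pair. Proportions are
#' percentages rounded half-up to 2 decimal places only in the `pct_2dp`
#' presentation column.
#'
#' @param row_labels,col_labels Equal-length label vectors (e.g. stakeholder
#'   group vs topic).
#' @return Tibble with `row`, `col`, `n`, `row_total`, `proportion`,
#'   `pct_2dp`.
#' @export
crosstab <- function(row_labels, col_labels) {
  if (length(row_labels) != length(col_labels)) {
    stop("label vectors differ in length")
  }
  df <- tibble::tibble(row = row_labels, col = col_labels)
  out <- dplyr::summarise(dplyr::group_by(df, .data$row, .data$col),
                          n = dplyr::n(), .groups = "drop")
  totals <- dplyr::summarise(dplyr::group_by(out, .data$row),
                             row_total = sum(.data$n), .groups = "drop")
  out <- dplyr::left_join(out, totals, by = "row")
  out$proportion <- out$n / out$row_total
  out$pct_2dp <- round_half_up(100 * out$proportion, 2L)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Run the full content-analysis pipeline
#'
#' Orchestrates the three analyses over a corpus:
#' * **stakeholder** — merge messages per member, build F1-F4 features,
#'   select or fix the number of clusters, fit the EM mixture, extract
#'   cluster keywords, and (when reference labels are available) compute
#'   partition metrics;
#' * **topic** — split off informational messages, build F2+F3 features over
#'   them, cluster, extract keywords, and cross-tabulate stakeholder group
#'   against topic cluster;
#' * **sentiment** — score every message, report the three measures per
#'   stakeholder group and per group x topic cell, polarity cross-tabs, and
#'   half-month trend series.
#'
#' All outputs are returned in a bundle and, when `out_dir` is given, written
#' as TSV/JSON files along with a run manifest (config echo, seed, package
#' version, output list).
#'
#' @param corpus A `forum_corpus` (raw; preprocessing is applied here).
#' @param lex Term lexicon ([load_term_lexicon()]).
#' @param senti_lex Sentiment lexicon ([load_sentiment_lexicon()]).
#' @param task `"stakeholder"`, `"topic"`, `"sentiment"`, or `"all"`.
#' @param k Number of clusters, or `"auto"` for cross-validated selection.
#' @param k_max,folds Model-selection controls when `k = "auto"`.
#' @param tau Subjectivity threshold for the informational/emotional split.
#' @param seed Integer seed for all stochastic stages.
#' @param ref_members Optional reference member labels
#'   (`author_id`, `forum`, `group`) for partition metrics.
#' @param ref_messages Optional reference message labels
#'   (`message_id`, `topic`) for topic partition metrics.
#' @param top_k Keywords reported per cluster.
#' @param out_dir Optional output directory.
#' @return A list bundle; see details of each element in the pipeline
#'   vignette.
#' @export
run_pipeline <- function(corpus, lex, senti_lex,
                         task = c("all", "stakeholder", "topic", "sentiment"),
                         k = "auto", k_max = 6L, folds = 10L, tau = 1.0,
                         seed = 1L, ref_members = NULL, ref_messages = NULL,
                         top_k = 20L, out_dir = NULL) {
  task <- match.arg(task)
  bundle <- list(seed = seed, task = task)
  corpus <- preprocess(corpus)
  bundle$descriptives <- descriptive_stats(corpus)

  members <- merge_by_author(corpus)
  member_group <- NULL

  if (task %in% c("all", "stakeholder")) {
    X <- build_feature_matrix(members, feature_spec(), lex = lex)
    k_stake <- if (identical(k, "auto")) {
      sel <- select_k(X, k_max = k_max, folds = folds, seed = seed)
      bundle$stakeholder_cv <- sel$cv_table
      sel$k
    } else as.integer(k)
    fit <- fit_em(X, k_stake, seed = seed)
    labels <- fit$assignment$labels
    member_group <- tibble::tibble(author_id = members$author_id,
                                   forum = members$forum,
                                   cluster = labels)
    freq <- cluster_term_frequencies(members$merged_text, labels)
    scores <- keyword_score(freq)
    bundle$stakeholder <- list(
      k = k_stake, model = fit$model, assignment = fit$assignment,
      members = member_group,
      keywords = lapply(stats::setNames(seq_len(k_stake), seq_len(k_stake)),
                        function(i) top_keywords(scores, i, k = top_k)))
    if (!is.null(ref_members)) {
      ref <- dplyr::left_join(member_group, ref_members,
                              by = c("author_id", "forum"))
      bundle$stakeholder$metrics <-
        partition_metrics(member_group$cluster, ref$group)
      bundle$stakeholder$t_tests <- cluster_t_tests(X, fit$assignment)
    }
  }

  split <- filter_informational(corpus, senti_lex, tau = tau)
  bundle$informational_split <- list(
    n_informational = nrow(split$informational),
    n_emotional = nrow(split$emotional))

  if (task %in% c("all", "topic")) {
    info <- split$informational
    if (nrow(info) < folds) stop("too few informational messages")
    # message-level n-gram pruning scales with corpus size (0.4% doc freq,
    # floor 3), keeping the feature space desk-scale
    topic_spec <- feature_spec(families = c("F2", "F3"),
                               min_doc_freq = max(3L,
                                                  ceiling(0.004 * nrow(info))))
    Xt <- build_feature_matrix(info, topic_spec, lex = lex)
    k_topic <- if (identical(k, "auto")) {
      sel <- select_k(Xt, k_max = max(k_max, 8L), folds = folds, seed = seed)
      bundle$topic_cv <- sel$cv_table
      sel$k
    } else as.integer(k)
    fit_t <- fit_em(Xt, k_topic, seed = seed)
    topic_labels <- tibble::tibble(message_id = info$message_id,
                                   cluster = fit_t$assignment$labels)
    freq_t <- cluster_term_frequencies(info$text, fit_t$assignment$labels)
    scores_t <- keyword_score(freq_t)
    bundle$topic <- list(
      k = k_topic, model = fit_t$model, assignment = fit_t$assignment,
      messages = topic_labels,
      keywords = lapply(stats::setNames(seq_len(k_topic), seq_len(k_topic)),
                        function(i) top_keywords(scores_t, i, k = top_k)))
    if (!is.null(ref_messages)) {
      ref <- dplyr::left_join(topic_labels, ref_messages, by = "message_id")
      bundle$topic$metrics <- partition_metrics(topic_labels$cluster,
                                                ref$topic)
    }
    if (!is.null(member_group)) {
      mg <- dplyr::left_join(
        tibble::tibble(author_id = info$author_id, forum = info$forum,
                       message_id = info$message_id),
        member_group, by = c("author_id", "forum"))
      bundle$topic$group_by_topic <- crosstab(mg$cluster,
                                              topic_labels$cluster)
    }
  }

  if (task %in% c("all", "sentiment")) {
    scored <- score_corpus(corpus, senti_lex)
    group_of <- if (!is.null(member_group)) {
      key <- dplyr::left_join(
        tibble::tibble(author_id = corpus$author_id, forum = corpus$forum),
        member_group, by = c("author_id", "forum"))
      as.character(key$cluster)
    } else corpus$forum
    polarity <- classify_polarity(scored)
    emo_mask <- scored$subjective_sum >= tau
    bundle$sentiment <- list(
      per_message = tibble::tibble(message_id = corpus$message_id,
                                   scored[, -1L], polarity = polarity),
      measures_by_group = sentiment_measures(scored, group_of),
      emotional_by_group = crosstab(group_of,
                                    ifelse(emo_mask, "emotional",
                                           "informational")),
      polarity_by_group = crosstab(group_of[emo_mask & polarity != "neutral"],
                                   polarity[emo_mask & polarity != "neutral"]),
      trends = trend_series(corpus, scored, group_of))
  }

  if (!is.null(out_dir)) {
    bundle$manifest <- .write_bundle(bundle, out_dir)
  }
  bundle
}

.write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  basename(path)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  files <- c(files, .write_tsv(bundle$descriptives,
                               file.path(out_dir, "descriptives.tsv")))
  if (!is.null(bundle$stakeholder)) {
    files <- c(files, .write_tsv(bundle$stakeholder$members,
                                 file.path(out_dir, "stakeholder_labels.tsv")))
    kw <- dplyr::bind_rows(bundle$stakeholder$keywords, .id = "cluster")
    files <- c(files, .write_tsv(kw, file.path(out_dir,
                                               "stakeholder_keywords.tsv")))
  }
  if (!is.null(bundle$topic)) {
    files <- c(files, .write_tsv(bundle$topic$messages,
                                 file.path(out_dir, "topic_labels.tsv")))
    kw <- dplyr::bind_rows(bundle$topic$keywords, .id = "cluster")
    files <- c(files, .write_tsv(kw, file.path(out_dir,
                                               "topic_keywords.tsv")))
  }
  if (!is.null(bundle$sentiment)) {
    files <- c(files,
               .write_tsv(bundle$sentiment$per_message,
                          file.path(out_dir, "sentiment_messages.tsv")),
               .write_tsv(bundle$sentiment$measures_by_group,
                          file.path(out_dir, "sentiment_measures.tsv")),
               .write_tsv(bundle$sentiment$trends,
                          file.path(out_dir, "sentiment_trends.tsv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("stakeminer")),
    seed = bundle$seed, task = bundle$task, outputs = files,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
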
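# stakeminer

Content analysis for online health community forums. Given a corpus of
forum messages (JSONL or CSV: `message_id`, `author_id`, `forum`,
`timestamp`, `text`), the package answers three questions that community
text alone can answer when user profiles cannot:

1. **Who is posting?** Members are clustered into stakeholder groups —
   patients (first-person symptom talk), caregivers (kinship terms,
   third-person pronouns), health specialists (second-person advice, very
   high posting volume) — by fitting a diagonal Gaussian mixture with EM
   over four textual feature families: writing style (F1), word n-grams
   (F2), medical terminology (F3), and kinship terminology (F4). The number
   of clusters is chosen by cross-validated forward search over the
   held-out log-likelihood.
2. **What are they talking about?** Emotional-support messages are split
   off by a lexicon subjectivity threshold, and the remaining informational
   messages are clustered over F2+F3 to find hot topics (symptom,
   examination, procedure, drug, complication in the packaged synthetic
   corpora).
3. **How do they feel?** SentiWordNet-style lexicon scores per message feed
   three group measures — PositiveScores, NegativeScores, SubjectiveScores
   (sums of matched term intensities divided by the number of messages) —
   plus positive/negative message shares and half-month trend series over
   each member's first year.

Clusters are *described*, not named: per-cluster keywords are ranked by the
score

    score(w, C_i) = f(w, C_i) * ln( N / |{ j : f(w, C_j) >= f(w, C_i) }| )

(frequency times log inverse cluster-rank), and a human reads the keyword
lists to label the clusters. Partition quality against reference labels is
measured with the pair-counting Rand, Jaccard, and Fowlkes–Mallows indices,
and cluster differences with Welch's two-sample t test.

Because real health-forum crawls are not redistributable, the package ships
a synthetic corpus generator with planted stakeholder groups, topic
vocabularies, posting-volume skew, and sentiment structure, plus gold
labels, so the entire pipeline is testable offline. Packaged lexicons
(medical/kinship term lists keyed by UMLS-style semantic types and a
sentiment lexicon in SentiWordNet 3.0 file layout) are synthetic fixtures;
real exports in the same formats drop in.

## Worked example

```r
library(stakeminer)

lex  <- load_term_lexicon(stakeminer_lexicon("terms"))
slex <- load_sentiment_lexicon(stakeminer_lexicon("sentiment"))

# default generator: one diabetes-like forum, 232 members, skewed volume
g <- generate_corpus(synth_config(seed = 42))
bundle <- run_pipeline(g$corpus, lex, slex, task = "all", k = "auto",
                       seed = 42, ref_members = g$members)

bundle$stakeholder$k
#> [1] 3
bundle$stakeholder$metrics
#> $rand
#> [1] 0.984326
#> $jaccard
#> [1] 0.9638896
#> $fm
#> [1] 0.9816143

head(bundle$stakeholder$keywords[[3]], 5)
#> # A tibble: 5 × 4
#>    rank term           freq score
#>   <int> <chr>         <dbl> <dbl>
#> 1     1 breath           28  30.8
#> 2     2 of breath        28  30.8
#> 3     3 out of breath    27  29.7
#> 4     4 feel             23  25.3
#> 5     5 i feel           23  25.3

bundle$sentiment$measures_by_group
#> # A tibble: 3 × 5
#>   group n_messages positive_scores negative_scores subjective_scores
#>   <chr>      <int>           <dbl>           <dbl>             <dbl>
#> 1 1            150          0.0723           0.158             0.231
#> 2 2            368          0.320            0.220             0.540
#> 3 3            156          0.130            0.355             0.486
```

Cross-validated selection finds the three planted populations (k = 3), and
the hard labels agree with the gold labels at Rand 0.98 / Jaccard 0.96 /
Fowlkes–Mallows 0.98. Keyword lists are how an analyst names clusters:
cluster 3 above is first-person lay symptom talk ("out of breath",
"i feel") — patients; cluster 1's list (not shown) leads with kinship
phrases ("my father", "know about") — caregivers; cluster 2 with
second-person advice ("your doctor", "need to", "ask") — specialists. The
sentiment table gives each cluster's per-message positive, negative and
subjective means; `subjective = positive + negative` holds exactly by
construction.

A thin command-line wrapper ships in `inst/cli/stakeminer.R`:

```sh
Rscript inst/cli/stakeminer.R synth --preset tiny --seed 1 --out demo
Rscript inst/cli/stakeminer.R run --in demo/corpus.jsonl --task all \
    --k auto --seed 1 --out demo_out
```

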
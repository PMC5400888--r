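---
title: "Methods: stakeholder, topic, and sentiment analysis of health forum text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stakeholder, topic, and sentiment analysis of health forum text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stakeminer)
```

## The problem

Online health communities mix three kinds of participants: patients writing
about their own condition in the first person, caregivers writing about a
family member (kinship terms, third-person pronouns), and health specialists
who answer in the second person and post far more often than anyone else.
Profiles rarely say which is which, so the three populations must be
inferred from the text itself. `stakeminer` implements a three-part content
analysis for such corpora:

1. **Stakeholder identification.** All messages by one author are merged
   into a member document; member documents are clustered with an EM-fitted
   mixture model over four feature families; per-cluster keywords are
   extracted so a human can name the clusters.
2. **Topic identification.** Messages offering only emotional support are
   filtered out by a subjectivity threshold; the remaining informational
   messages are clustered over n-gram and medical-terminology features, and
   keywords per cluster identify the hot topics.
3. **Sentiment measurement.** Lexicon scores per message feed three
   group-level measures and half-month trend series over each member's
   first year.

## Text model and features

One tokenizer underlies everything: lowercase, URL/markup stripping, word
tokens as maximal runs of letters/digits/apostrophes. Sentences are split
on terminal punctuation with a small abbreviation guard; messages without
terminal punctuation count as one sentence. All lexicon matching and all
n-gram counting are defined over exactly these tokens, so counts agree
across modules.

Four feature families enter the unit-by-feature matrix
(`build_feature_matrix()`):

* **F1 style** (member documents only): message count, mean sentences per
  message, mean words per message. "Frequency of words per message" is
  implemented as the scalar mean words per message.
* **F2 n-grams**: word unigrams, bigrams, trigrams; columns pruned by
  document frequency (`min_doc_freq`, default 3) and capped by total
  frequency (`vocabulary_cap`, default 5000, ties broken lexicographically).
* **F3 medical terminology**: counts of dictionary terms carrying
  UMLS-style semantic-type codes (sosy, dsyn, patf, diap, topp, phsu,
  lbpr). The packaged lexicon is a synthetic stand-in organized by those
  codes; a real MeSH/UMLS export in the same three-column TSV layout can be
  dropped in.
* **F4 kinship terminology**: counts of family-group (famg) terms.

Terminology matching is greedy longest-match left to right, so
"father in law" never double-counts "father". F3/F4 columns are counts, not
binary indicators: usage frequency carries group signal.

## Mixture model

Clustering uses a diagonal Gaussian mixture fitted by EM (`fit_em()`).
Count-family columns are log1p-transformed; style columns enter raw. The
diagonal (per-feature independence) form is what keeps thousands of n-gram
columns tractable.

Numerical choices that matter:

* **Variance shrinkage.** Component variances are shrunk toward the global
  per-feature variance with `var_prior = 2` pseudo-observations and floored
  at `var_floor_frac = 0.08` of the global variance (hard floor
  `scale_floor = 1e-6` underneath). Without this, a component that happens
  to be constant on a sparse column collapses onto it and held-out
  likelihoods explode, which wrecks cross-validated model selection. The
  floor fraction was calibrated once on synthetic corpora so that
  cross-validation neither collapses to one component (floor too low: every
  split is punished by variance overfit) nor grows without bound (floor too
  high: extra components are never penalized). With `var_prior = 0` and
  `var_floor_frac = 0` the fit is plain maximum-likelihood EM, whose
  log-likelihood trace is exactly non-decreasing; the default lightly
  penalized fit tracks that property to numerical tolerance.
* **Initialization.** High-dimensional sparse text mixtures have many poor
  local optima, and k-means on raw standardized features reliably finds one
  of them (it splits on posting volume, not on vocabulary). Restarts are
  therefore structured: k-means in cosine geometry (row-normalized
  documents), a spectral partition of the cosine affinity (for small unit
  counts) or k-means on a randomized latent-semantic embedding (for large
  ones), then random soft splits, with the final fit chosen by training
  log-likelihood. On synthetic corpora the planted partition has by far the
  highest likelihood; the structured inits are what lets EM find its basin.
* **Convergence.** Relative log-likelihood change below `tol = 1e-6`, at
  most `max_iter = 200` iterations, `n_init = 5` restarts for final fits
  and 2 inside cross-validation.

**Model selection** (`select_k()`) mirrors cross-validated EM as popular
desktop tools implement it: for K = 1, 2, ... compute the mean held-out
log-likelihood per unit over 10 folds, stop at the first K that fails to
improve, and return K − 1. Hard labels are the posterior argmax with ties
to the lowest index.

**Evaluation** uses the three pair-counting partition metrics (Rand,
Jaccard, Fowlkes–Mallows) computed from the label contingency table; a
brute-force O(n²) pair enumeration serves as the test oracle. Pairwise
cluster differences are assessed with Welch's two-sample t test on
posterior-weighted per-member feature summaries; the choice of summary is a
package decision, since only the test itself is prescribed.

## Keyword scoring

For term *w* and cluster *C<sub>i</sub>* among *N* clusters with raw
cluster frequencies *f(w, C<sub>i</sub>)*:

score(w, C<sub>i</sub>) = f(w, C<sub>i</sub>) · ln( N / m ),
m = #{ j : f(w, C<sub>j</sub>) ≥ f(w, C<sub>i</sub>) }.

The cluster itself always counts, so m ≥ 1; a term equally frequent
everywhere scores 0, and only a strict maximum reaches f·ln N. The log base
is natural: ranking is base-invariant, absolute scores are nat-scaled.
Keyword lists drop an n-gram only when *all* its tokens are stopwords, so
phrases like "thank you" survive while bare function words do not.

## Sentiment

The sentiment lexicon maps a term to aggregated positive and negative
intensities in [0, 1]. The reader accepts the SentiWordNet 3.0 file layout
or a simple 3-column TSV; multiple senses aggregate by rank weighting
(sum(score/rank) / sum(1/rank)) by default, with `mean` and `first_sense`
alternatives. No negation or valence-shifter handling: scoring is pure
additive lexicon lookup, matching the pipeline's design.

A message's subjective sum is pos + neg exactly; a message is *emotional*
when that sum reaches the threshold `tau`, default 1.0 (the threshold is a
config knob; with intensities around 0.6–0.9 per strong sentiment word,
1.0 amounts to "at least two clearly subjective words or one very strong
pair"). Group measures are pooled per-message means (PositiveScores,
NegativeScores, SubjectiveScores = their sum). Message polarity compares
the two sums, ties neutral; neutral messages are excluded from
positive/negative share denominators. Trend series use half-open 15-day
bins from each author's first post, bins 0–23, so day 360 and later fall
outside the first year.

## The synthetic forum generator

Because real crawls of health communities are not redistributable, the
package ships a generator (`generate_corpus()`) that plants exactly the
structure the pipeline is built to detect, with gold labels emitted
separately so the pipeline can never read them implicitly. Text is
template-based slot filling — controllable, inspectable, lexical — not a
language model. It emulates:

* three author populations with distinct voices: first-person symptom talk
  (patients), kinship terms plus third-person pronouns (caregivers),
  second-person advice with far higher posting volume (specialists);
* five topic vocabularies keyed to semantic-type term pools (symptom,
  complication, examination, procedure, drug), with Zipf-weighted term
  usage: a few everyday terms dominate and a long tail of rarer
  terminology falls below n-gram document-frequency cutoffs, which is what
  gives the exhaustive lexicon matcher (F3) information the pruned n-gram
  vocabulary (F2) lacks;
* group-graded lay vocabulary: each topic-term slot is replaced by a lay
  paraphrase ("blood work", "my pills") with a per-group probability
  (patients 0.65, caregivers 0.25, specialists 0.05 by default), encoding
  the observation that lay participants use everyday words where
  professionals use terminology — the rationale for the terminology
  feature family;
* skewed posting volume via shifted-Poisson message counts per member;
* per-group emotional-message probabilities and polarity mixes, with
  sentiment-term intensities placed so emotional messages always clear the
  default subjectivity threshold and informational ones never do, and an
  optional linear polarity trend over each member's first year.

Presets: `tiny` (60 members, smoke tests), `paperlike` (three forums whose
group ratios and per-group posting volumes mirror a large public health
community at 1/50 scale, ~790 members), and `topiclike` (one forum sized to
yield roughly 2,000 informational messages for the topic task; its
informational text is mostly neutral-voiced factual content with a uniform
lay rate across groups, so the dominant planted structure at the message
level is the topic vocabulary). Template pools are deliberately varied (12
informational and 6 emotional skeletons per group, emotional posts
interleaving group phrases with topic mentions): with too few skeletons, or
with emotional vocabulary disjoint from informational vocabulary, member
documents cluster by skeleton or by venting-versus-asking rather than by
population, which no real corpus does.

What the generator does **not** emulate: realistic English fluency, thread
and reply structure, vocabulary drift over time, misspellings, author-level
style idiosyncrasies, or topic correlation within authors. Passing tests
on synthetic corpora therefore demonstrate that the pipeline recovers
planted lexical structure under realistic size and skew — not performance
on real forum text.

## Problem sizes in the tests and acceptance runs

The packaged checks run the stakeholder task on single-forum corpora of
about 230 members (~700 messages) and the topic task on about 2,000
informational messages, each over 20 seeded replicates for model-count
recovery, with 10-fold cross-validation up to k_max = 6 (members) or 8
(messages). The feature-ablation sweep (F1 → F1+F2 → F1+F2+F3 →
F1+F2+F3+F4) averages the three partition metrics over five seeded corpora
at the planted K = 3. For the topic task the n-gram document-frequency
cutoff scales with corpus size (0.4% of messages, floor 3), a standard
message-level pruning choice that keeps the feature space in the low
thousands.

## Known limitations

* The informational/emotional threshold and the noise-filtering rules are
  config knobs; no published values exist to pin them.
* Partition metrics require reference labels; on real data these must be
  supplied (e.g., an annotated subset). The package computes them against
  planted or user-provided labels only.
* The t statistic's input quantity in cluster comparisons is a package
  decision (posterior-weighted feature summaries), as only the test itself
  is prescribed by the method the package follows.
* Sense aggregation for the sentiment lexicon defaults to rank weighting;
  other conventions change absolute scores (not orderings in our tests).
* EM with structured initialization is a local optimizer; on data with
  weaker separation than the synthetic defaults, restarts (`n_init`) may
  need to be increased.
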
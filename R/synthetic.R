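# Synthetic forum-corpus generator. Emulates the structure the pipeline is
# built to detect: three author populations (patients, caregivers,
# specialists) with distinct phrase/pronoun/terminology usage, five topic
# vocabularies keyed to semantic-type term pools, heavily skewed posting
# volume (specialists post an order of magnitude more than patients or
# caregivers), and a controllable mix of informational and emotional
# messages with per-group polarity and an optional linear polarity trend
# over each member's first year. Text is template-based slot filling: every
# generated signal is lexical, inspectable, and labeled, and gold labels are
# returned separately so the pipeline can never read them implicitly.

.groups <- c("patient", "caregiver", "specialist")
.topics <- c("symptom", "complication", "examination", "procedure", "drug")

# Term usage within a pool is Zipf-weighted: a handful of everyday terms
# plus a long tail of rarer terminology, as in real communities. Tail terms
# usually fall below n-gram document-frequency cutoffs, so the exhaustive
# lexicon matcher (F3) sees terminology that the pruned n-gram vocabulary
# (F2) does not.
.topic_pools <- list(
  symptom = c("cough", "pain", "breathless", "wheezing", "nausea", "fatigue",
              "thirsty", "tired", "dizzy", "itchy", "sore", "tingling",
              "chest pain", "shortness of breath", "hot flashes",
              "frequent urination", "nipple discharge", "hungry",
              "hoarseness", "night sweats", "weight loss",
              "loss of appetite", "numbness", "headache", "blurred vision",
              "dry mouth", "chills", "fever", "back pain", "joint pain",
              "palpitations", "sweating", "insomnia", "swollen ankles"),
  complication = c("infection", "bronchitis", "pneumonia", "tuberculosis",
                   "asthma", "pleural effusion", "copd", "emphysema",
                   "atelectasis", "hypoglycemia", "obesity", "kidney disease",
                   "diabetic neuropathy", "rash", "mastitis", "eczema",
                   "neuropathy", "lymph edema", "complex cyst", "coma",
                   "sepsis", "anemia", "dehydration", "ketoacidosis",
                   "retinopathy", "nephropathy", "gastroparesis",
                   "cellulitis", "pulmonary embolism", "pleurisy",
                   "hypercalcemia", "bone metastasis", "brain metastasis",
                   "thrush", "shingles", "foot ulcers"),
  examination = c("biopsy", "mri", "ultrasound", "mammogram", "screening",
                  "x-ray", "cat scan", "pet scan", "imaging", "bronchoscopy",
                  "blood test", "glucose test", "fasting test",
                  "glucose tolerance test", "hemoglobin a1c test",
                  "chest x-ray", "core biopsy", "fasting blood sugar",
                  "ct scan", "bone scan", "echocardiogram", "spirometry",
                  "tumor marker test", "cea test", "c peptide test",
                  "microalbumin test", "lipid panel", "thyroid panel",
                  "liver panel", "sputum cytology",
                  "fine needle aspiration", "ekg", "bone density scan"),
  procedure = c("chemo", "operation", "surgery", "radiation", "therapy",
                "chemotherapy", "removal", "radiation therapy", "lobectomy",
                "mastectomy", "lumpectomy", "infusion", "injection",
                "transplant", "dialysis", "insulin injection", "amputation",
                "wedge resection", "radiotherapy", "implant",
                "port placement", "stent placement", "cryotherapy",
                "brachytherapy", "reconstruction", "axillary dissection",
                "oophorectomy", "thoracentesis", "pleurodesis",
                "bypass surgery", "laser therapy", "physical therapy",
                "insulin pump therapy", "gastric bypass"),
  drug = c("insulin", "metformin", "lantus", "januvia", "glucophage",
           "actos", "avandia", "amaryl", "glipizide", "tamoxifen",
           "arimidex", "taxol", "femara", "taxotere", "carboplatin",
           "morphine", "advil", "tarceva", "chantix", "alimta", "dilaudid",
           "coumadin", "effexor", "docetaxel", "valium", "raloxifene",
           "gemcitabine", "cisplatin", "etoposide", "paclitaxel",
           "bevacizumab", "erlotinib", "gefitinib", "afatinib", "pemetrexed",
           "vinorelbine", "topotecan", "irinotecan", "capecitabine",
           "anastrozole", "letrozole", "exemestane", "fulvestrant",
           "trastuzumab", "lapatinib", "palbociclib", "glimepiride",
           "pioglitazone", "sitagliptin", "liraglutide", "exenatide",
           "canagliflozin", "dapagliflozin", "acarbose", "repaglinide",
           "gabapentin", "tramadol", "oxycodone", "prednisone")
)

# Lay paraphrases per topic: vocabulary real patients use where a
# professional would use terminology. None of these phrases appear in the
# packaged medical lexicon, so heavier lay usage means fewer terminology
# matches for the same topical content.
.lay_pools <- list(
  symptom = c("feeling off", "worn out", "run down", "no energy",
              "out of breath"),
  complication = c("a nasty bug", "low sugar spells", "kidney trouble",
                   "breathing trouble", "swelling that stays"),
  examination = c("blood work", "the scans", "test results",
                  "follow up pictures"),
  procedure = c("the treatments", "the needles", "the drip",
                "getting it taken out"),
  drug = c("my pills", "my meds", "the shots", "my prescription")
)

.kinship_pool <- c("husband", "wife", "mother", "father", "mom", "dad",
                   "son", "daughter", "sister", "brother", "father in law",
                   "mother in law", "grandmother", "aunt")

.pos_terms <- c("good", "great", "happy", "glad", "hopeful", "wonderful",
                "thankful", "grateful", "blessed", "relieved", "encouraging",
                "lucky")
.neg_terms <- c("worried", "scared", "afraid", "anxious", "sad", "depressed",
                "terrible", "awful", "hopeless", "devastated", "stressed",
                "frustrated")

# Informational message skeletons. {kin} = kinship term, {tN} = topic terms.
.info_templates <- list(
  patient = c(
    "i was diagnosed with {t1} and i have {t2} in my chest.",
    "my {t1} is getting worse and my {t2} was scheduled. what should i do about the {t3}?",
    "i was wondering about {t1} after my {t2}.",
    "my question is about {t1} and {t2}. i had {t3} last week.",
    "i have {t1} and {t2}. please help me understand the {t3} results.",
    "my doctor mentioned {t1}. does {t2} explain my {t3}?",
    "i am on {t1} now and my {t2} has not changed. should i ask about {t3}?",
    "i noticed {t1} after my {t2}. i am due for a {t3} next month.",
    "can anyone tell me if {t1} causes {t2}? i go back for my {t3} soon.",
    "i just got my {t1} results and they mention {t2}. what does that mean for me?",
    "since my {t1} started i keep track of my {t2}. my {t3} is next week.",
    "does anyone else have {t1} with {t2}? my {t3} was inconclusive."
  ),
  caregiver = c(
    "my {kin} was diagnosed with {t1} and she has {t2} now.",
    "my {kin} had {t1} last week and his {t2} showed {t3}.",
    "my {kin} is on {t1} and her {t2} is getting worse. she needs help.",
    "want to know about {t1} for my {kin}. he had {t2} and his {t3} is back.",
    "his {t1} and his {t2} were discussed. she wants my {kin} to get the {t3} explained.",
    "she has been having {t1} since her {t2}. my {kin} needs the {t3} explained.",
    "my {kin} just started {t1}. her {t2} numbers moved and the doctor ordered a {t3}.",
    "does {t1} help with {t2}? my {kin} is scheduled for {t3} and she keeps asking.",
    "he was told {t1} could cause {t2}. my {kin} wants to know about the {t3}.",
    "she cannot manage her {t1}. my {kin} got a different {t2} after the {t3}.",
    "she goes in for {t1} tomorrow. my {kin} already had {t2} and {t3}.",
    "his {t1} came back. what should my {kin} expect from {t2} and the {t3}?"
  ),
  specialist = c(
    "you should ask your doctor about {t1} and {t2}.",
    "your {t1} and {t2} results need to be reviewed. you need to schedule a {t3}.",
    "i would suggest {t1} and a {t2}. let us know about the {t3}.",
    "with your doctor you can discuss {t1} and whether {t2} is indicated.",
    "you could consider {t1}. your {t2} may explain the {t3}. hope this helps.",
    "you need to have the {t1} repeated. a {t2} would rule out {t3}.",
    "ask about {t1} at your next visit. your {t2} history matters for the {t3}.",
    "you may want a second opinion on {t1}. your {t2} and {t3} should be monitored.",
    "keep a log of your {t1}. if the {t2} persists you should request a {t3}.",
    "that reading is common with {t1}. you can ask your doctor whether {t2} or {t3} applies.",
    "your {t1} plan depends on the {t2}. you should not stop {t3} on your own.",
    "it would help to repeat the {t1}. your {t2} may be from the {t3}."
  )
)

# Neutral factual skeletons: informational posts that carry no group voice,
# only topic content. The share of informational messages written this way
# is the config knob `neutral_info_prob`.
.neutral_templates <- c(
  "the {t1} was reviewed along with the {t2}. the {t3} comes next.",
  "{t1} and {t2} often go together. a {t3} can clarify.",
  "after {t1} the usual step is {t2}. the {t3} results take about a week.",
  "notes from the visit: {t1}, {t2}, and the {t3} were discussed.",
  "the clinic explained {t1} and {t2}. a follow up {t3} was arranged.",
  "an update: the {t1} is stable and the {t2} was repeated. next is the {t3}."
)

# Emotional message skeletons. {sN} = sentiment terms of the drawn polarity.
# Emotional posts still speak in the group's voice and mention the member's
# topic, so emotional and informational messages by the same population
# share vocabulary.
.emo_templates <- list(
  patient = c(
    "thank you so much. i feel {s1} and {s2} about the {t1}. my question is about {t2}.",
    "please help me, i am {s1} and {s2} about this {t1}. i was wondering about {t2}.",
    "i am {s1} and {s2} since i was diagnosed with {t1}. any advice would be greatly appreciated.",
    "honestly i feel {s1} and {s2} today. my {t1} and {t2} are on my mind.",
    "i want to thank you all. i feel {s1} and {s2} after reading about {t1} here.",
    "i cannot stop being {s1} and {s2} about my {t1}. my {t2} is coming up."
  ),
  caregiver = c(
    "i am {s1} and {s2} and {s3} about my {kin}. she has {t1} now. thanks so much.",
    "my {kin} makes me feel {s1} and {s2} and {s3}. his {t1} and the {t2} keep us up. thanks in advance.",
    "caring for my {kin} leaves me {s1} and {s2} and {s3}. her {t1} is getting worse.",
    "we are {s1} and {s2} and {s3} about the {t1} for my {kin}. he starts {t2} soon.",
    "watching my {kin} go through {t1} leaves us {s1} and {s2} and {s3}.",
    "my {kin} had her {t1} today. i am {s1} and {s2} and {s3} waiting for the {t2}."
  ),
  specialist = c(
    "stay positive. wishing you {s1} and {s2} and {s3} days ahead. your {t1} should settle. all the best.",
    "sorry to hear about the {t1}. this sounds {s1} and {s2} and {s3}. you should discuss {t2} with your doctor.",
    "good luck, this is {s1} and {s2} and {s3} news. your {t1} and {t2} look fine. god bless.",
    "that is {s1} and {s2} and {s3}. you need to keep the {t1} going. let us know.",
    "i understand this feels {s1} and {s2} and {s3}. your {t1} team sees this often. stay the course.",
    "these results are {s1} and {s2} and {s3}. you should review the {t1} with your doctor."
  )
)

#' Synthetic forum generator configuration
#'
#' All distributional knobs of the generator in one validated object.
#' Defaults mirror the structure of a large public health community: three
#' stakeholder populations with distinct phrase templates, five topic
#' vocabularies keyed to semantic-type term pools, a posting-volume skew of
#' roughly an order of magnitude in favor of specialists, per-group
#' emotional-message probabilities, and per-group polarity mixes with an
#' optional linear trend over each member's first year.
#'
#' @param seed Integer seed; generation is fully deterministic given the
#'   config (including this seed).
#' @param forums Named list; each element is
#'   `list(members = c(patient=, caregiver=, specialist=),
#'         messages_per_member = c(patient=, caregiver=, specialist=))`
#'   where `messages_per_member` gives the mean of a shifted Poisson
#'   (`1 + rpois(mean - 1)`).
#' @param topic_mixture Named list per group: probability over the five
#'   topics (`symptom`, `complication`, `examination`, `procedure`, `drug`);
#'   each must sum to 1.
#' @param emotional_prob Named numeric per group: probability a message is
#'   emotional rather than informational.
#' @param positive_share Named numeric per group: probability an emotional
#'   message is positive (at day 0 when a trend is set).
#' @param trend_slope Named numeric per group: linear increase of the
#'   positive share over the first 360 days (0 = stationary).
#' @param topic_terms_per_message Number of topic-term slots filled per
#'   informational message (templates use up to 3; default 3). Terms beyond
#'   the third are appended as a neutral factual elaboration sentence.
#' @param neutral_info_prob Probability that an informational message is
#'   written in a neutral factual voice (no group-specific phrasing);
#'   default 0 (every post carries its author group's voice). The
#'   topic-task preset raises it: informational support text is dominated
#'   by content, not by the author's voice.
#' @param lay_term_prob Named numeric per group: probability that a topic
#'   term slot is filled with a lay paraphrase instead of a lexicon
#'   terminology term. Patients and caregivers use more lay vocabulary than
#'   health professionals, which is what makes the terminology feature
#'   family informative about who is writing.
#' @param start_date Date of the earliest possible first post.
#' @param span_days Calendar span over which first posts are spread.
#' @param mean_gap_days Mean gap between a member's consecutive posts.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         forums = list(
                           diabetes = list(
                             members = c(patient = 115, caregiver = 97,
                                         specialist = 20),
                             messages_per_member = c(patient = 1.34,
                                                     caregiver = 1.48,
                                                     specialist = 20.43))),
                         topic_mixture = list(
                           patient = c(symptom = 0.32, complication = 0.13,
                                       examination = 0.25, procedure = 0.17,
                                       drug = 0.13),
                           caregiver = c(symptom = 0.22, complication = 0.20,
                                         examination = 0.20, procedure = 0.22,
                                         drug = 0.16),
                           specialist = c(symptom = 0.20, complication = 0.20,
                                          examination = 0.20, procedure = 0.20,
                                          drug = 0.20)),
                         emotional_prob = c(patient = 0.25, caregiver = 0.14,
                                            specialist = 0.21),
                         positive_share = c(patient = 0.35, caregiver = 0.38,
                                            specialist = 0.52),
                         trend_slope = c(patient = 0.3, caregiver = 0.25,
                                         specialist = 0),
                         topic_terms_per_message = 3L,
                         lay_term_prob = c(patient = 0.65, caregiver = 0.25,
                                           specialist = 0.05),
                         neutral_info_prob = 0,
                         start_date = "2014-01-01",
                         span_days = 720L,
                         mean_gap_days = 25) {
  cfg <- list(seed = as.integer(seed), forums = forums,
              topic_mixture = topic_mixture,
              emotional_prob = emotional_prob,
              positive_share = positive_share,
              trend_slope = trend_slope,
              topic_terms_per_message = as.integer(topic_terms_per_message),
              lay_term_prob = lay_term_prob,
              neutral_info_prob = neutral_info_prob,
              start_date = start_date, span_days = as.integer(span_days),
              mean_gap_days = mean_gap_days)
  problems <- character(0)
  if (cfg$neutral_info_prob < 0 || cfg$neutral_info_prob > 1) {
    problems <- c(problems, "neutral_info_prob outside [0,1]")
  }
  for (fn in names(cfg$forums)) {
    f <- cfg$forums[[fn]]
    if (!setequal(names(f$members), .groups) ||
        any(f$members < 0)) {
      problems <- c(problems, sprintf("forum %s: bad member counts", fn))
    }
    if (!setequal(names(f$messages_per_member), .groups) ||
        any(f$messages_per_member < 1)) {
      problems <- c(problems,
                    sprintf("forum %s: messages_per_member must be >= 1", fn))
    }
  }
  for (g in .groups) {
    mix <- cfg$topic_mixture[[g]]
    if (is.null(mix) || !setequal(names(mix), .topics) ||
        abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
      problems <- c(problems, sprintf("topic_mixture[%s] must be a probability vector over the five topics", g))
    }
    for (field in c("emotional_prob", "positive_share", "trend_slope",
                    "lay_term_prob")) {
      v <- cfg[[field]][[g]]
      if (is.null(v) || is.na(v)) {
        problems <- c(problems, sprintf("%s[%s] missing", field, g))
      }
    }
    if (!is.null(cfg$emotional_prob[[g]]) &&
        (cfg$emotional_prob[[g]] < 0 || cfg$emotional_prob[[g]] > 1)) {
      problems <- c(problems, sprintf("emotional_prob[%s] outside [0,1]", g))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid generator config:\n  ",
         paste(problems, collapse = "\n  "))
  }
  structure(cfg, class = "synth_config")
}

#' Named generator presets
#'
#' `tiny` — one forum, 60 members across the three groups, mild volume skew;
#' generates in well under a second and is the default smoke-test corpus.
#' `paperlike` — three disease forums whose group ratios and posting-volume
#' skew mirror a large public health community at 1/50 scale (about 790
#' members and 2,700 messages; specialists post 10-20x more per member than
#' patients). `topiclike` — a single forum sized so that roughly 2,000
#' informational messages are available for topic clustering.
#'
#' @param name One of `"tiny"`, `"paperlike"`, `"topiclike"`.
#' @param seed Seed stored in the config.
#' @return A `synth_config`.
#' @export
preset <- function(name = c("tiny", "paperlike", "topiclike"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    tiny = synth_config(
      seed = seed,
      forums = list(lung_cancer = list(
        members = c(patient = 25, caregiver = 20, specialist = 15),
        messages_per_member = c(patient = 2, caregiver = 2,
                                specialist = 6)))),
    paperlike = synth_config(
      seed = seed,
      forums = list(
        lung_cancer = list(
          members = c(patient = 24, caregiver = 21, specialist = 3),
          messages_per_member = c(patient = 1.15, caregiver = 1.53,
                                  specialist = 14.48)),
        diabetes = list(
          members = c(patient = 115, caregiver = 97, specialist = 20),
          messages_per_member = c(patient = 1.34, caregiver = 1.48,
                                  specialist = 20.43)),
        breast_cancer = list(
          members = c(patient = 350, caregiver = 127, specialist = 36),
          messages_per_member = c(patient = 1.55, caregiver = 1.53,
                                  specialist = 34.09)))),
    topiclike = synth_config(
      seed = seed,
      forums = list(mixed = list(
        members = c(patient = 180, caregiver = 140, specialist = 40),
        messages_per_member = c(patient = 5, caregiver = 5,
                                specialist = 22))),
      topic_terms_per_message = 8L,
      lay_term_prob = c(patient = 0.3, caregiver = 0.3, specialist = 0.3),
      neutral_info_prob = 0.6)
  )
}

.fill_template <- function(tpl, topic_terms, kin = NULL, senti = NULL) {
  out <- tpl
  for (i in seq_along(topic_terms)) {
    out <- sub(paste0("{t", i, "}"), topic_terms[i], out, fixed = TRUE)
  }
  # unused topic slots get another draw from the same terms
  while (grepl("\\{t[0-9]\\}", out)) {
    out <- sub("\\{t[0-9]\\}", topic_terms[1L], out)
  }
  if (!is.null(kin)) out <- gsub("{kin}", kin, out, fixed = TRUE)
  if (!is.null(senti)) {
    for (i in seq_along(senti)) {
      out <- sub(paste0("{s", i, "}"), senti[i], out, fixed = TRUE)
    }
  }
  out
}

#' Generate a synthetic forum corpus with gold labels
#'
#' Assembles messages by sampling group-specific template skeletons and
#' filling their slots with topic terms (semantic-type pools), kinship terms
#' (caregivers), and sentiment terms (emotional messages). Emotional
#' messages carry at least two sentiment terms of the drawn polarity, so
#' their subjective sum is always >= 1.2; informational messages carry at
#' most one weak sentiment word, keeping their subjective sum below 1.
#' Deterministic given the config (same config, same seed: byte-identical
#' corpus).
#'
#' @param cfg A `synth_config`.
#' @return List: `corpus` (a `forum_corpus`), `members` (gold stakeholder
#'   labels: `author_id`, `forum`, `group`), `messages` (gold message labels:
#'   `message_id`, `topic`, `emotional`, `polarity`), `config`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  origin <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = "UTC")
  m_author <- m_forum <- m_text <- m_topic <- m_polarity <- character(0)
  m_day <- numeric(0)
  m_emotional <- logical(0)
  u_author <- u_forum <- u_group <- character(0)
  uid <- 0L
  for (fn in names(cfg$forums)) {
    f <- cfg$forums[[fn]]
    for (g in .groups) {
      n_members <- f$members[[g]]
      if (n_members == 0) next
      mix <- cfg$topic_mixture[[g]][.topics]
      for (m in seq_len(n_members)) {
        uid <- uid + 1L
        author <- sprintf("u%05d", uid)
        n_msgs <- 1L + stats::rpois(1L, f$messages_per_member[[g]] - 1)
        first_day <- stats::runif(1L, 0, max(1, cfg$span_days - 370))
        gaps <- stats::rexp(n_msgs - 1L, rate = 1 / cfg$mean_gap_days)
        days <- first_day + c(0, cumsum(gaps))
        u_author <- c(u_author, author)
        u_forum <- c(u_forum, fn)
        u_group <- c(u_group, g)
        texts <- topics <- polarities <- character(n_msgs)
        emotionals <- logical(n_msgs)
        for (j in seq_len(n_msgs)) {
          topic <- sample(.topics, 1L, prob = mix)
          pool <- .topic_pools[[topic]]
          terms <- sample(pool, min(cfg$topic_terms_per_message,
                                    length(pool)),
                          prob = 1 / seq_along(pool))
          lay <- stats::runif(length(terms)) < cfg$lay_term_prob[[g]]
          if (any(lay)) {
            terms[lay] <- sample(.lay_pools[[topic]], sum(lay),
                                 replace = TRUE)
          }
          emotional <- stats::runif(1L) < cfg$emotional_prob[[g]]
          kin <- if (g == "caregiver") sample(.kinship_pool, 1L) else NULL
          day_offset <- days[j] - days[1L]
          extra <- if (length(terms) > 3L) terms[-(1:3)] else character(0)
          if (emotional) {
            p_pos <- min(0.95, max(0.05, cfg$positive_share[[g]] +
                           cfg$trend_slope[[g]] * min(day_offset, 360) / 360))
            polarity <- if (stats::runif(1L) < p_pos) "positive" else "negative"
            pool_s <- if (polarity == "positive") .pos_terms else .neg_terms
            n_senti <- if (g == "patient") 2L else 3L
            senti <- sample(pool_s, n_senti)
            tpl <- sample(.emo_templates[[g]], 1L)
            text <- .fill_template(tpl, terms, kin = kin, senti = senti)
          } else {
            polarity <- "neutral"
            tpl <- if (stats::runif(1L) < cfg$neutral_info_prob) {
              sample(.neutral_templates, 1L)
            } else {
              sample(.info_templates[[g]], 1L)
            }
            text <- .fill_template(tpl, terms, kin = kin)
            # topic elaboration beyond the template's three slots is written
            # in a neutral factual voice: a terse list of related findings,
            # leading with the message's main term again
            if (length(extra) > 0L) {
              text <- paste(text, paste0("also discussed: ",
                                         paste(c(terms[1L], extra),
                                               collapse = ", "),
                                         "."))
            }
          }
          texts[j] <- text
          topics[j] <- topic
          polarities[j] <- polarity
          emotionals[j] <- emotional
        }
        m_author <- c(m_author, rep(author, n_msgs))
        m_forum <- c(m_forum, rep(fn, n_msgs))
        m_day <- c(m_day, days)
        m_text <- c(m_text, texts)
        m_topic <- c(m_topic, topics)
        m_polarity <- c(m_polarity, polarities)
        m_emotional <- c(m_emotional, emotionals)
      }
    }
  }
  ids <- sprintf("msg%06d", seq_along(m_text))
  corpus <- as_corpus(
    tibble::tibble(message_id = ids, author_id = m_author, forum = m_forum,
                   timestamp = origin + round(m_day * 86400), text = m_text),
    provenance = list(generator = "stakeminer::generate_corpus",
                      seed = cfg$seed))
  list(corpus = corpus,
       members = tibble::tibble(author_id = u_author, forum = u_forum,
                                group = u_group),
       messages = tibble::tibble(message_id = ids, topic = m_topic,
                                 emotional = m_emotional,
                                 polarity = m_polarity),
       config = cfg)
}

#' Path to a packaged lexicon fixture
#'
#' @param which `"terms"` (medical + kinship TSV), `"sentiment"`
#'   (synthetic SentiWordNet-layout file), or `"sentiment_simple"`
#'   (3-column fixture).
#' @return File path inside the installed package.
#' @export
stakeminer_lexicon <- function(which = c("terms", "sentiment",
                                         "sentiment_simple")) {
  which <- match.arg(which)
  fname <- switch(which,
                  terms = "term_lexicon.tsv",
                  sentiment = "sentiwordnet_synthetic.txt",
                  sentiment_simple = "sentiment_simple.tsv")
  system.file("extdata", fname, package = "stakeminer", mustWork = TRUE)
}
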
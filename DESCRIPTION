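Package: stakeminer
Title: Stakeholder, Topic, and Sentiment Analysis for Online Health Community Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A content-analysis toolkit for online health community forums.
    Identifies stakeholder groups (patients, caregivers, health specialists)
    by expectation-maximization mixture clustering over a four-family textual
    feature set (writing style, word n-grams, medical terminology, kinship
    terminology), identifies hot health topics among informational messages,
    extracts cluster keywords by a frequency x inverse cluster-rank score,
    and measures lexicon-based sentiment (positive, negative, and subjective
    scores) per stakeholder group, including half-month trend series over
    each member's first year. Ships a synthetic forum-corpus generator with
    planted gold labels so the whole pipeline is testable without scraping
    any real community.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
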
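Package: lingdist
Title: Linguistic Distancing and Abstractness Scoring for Emotion Regulation Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores free-text responses from emotion-regulation experiments on
    two psycholinguistic dimensions: a linguistic distancing composite (z-scored
    rates of first-person singular pronouns, present-tense verbs, discrepancy
    words, articles, and long words, with the first three reverse-coded) and
    linguistic abstractness under the linguistic category model (weighted mean
    of word-class abstraction levels 1-5). Provides condition aggregation and
    delta-score construction for within-subject reappraisal designs and mixed
    distance-by-domain designs, an inferential layer (standardized-beta
    regression, repeated-measures and mixed ANCOVA with type III sums of
    squares, partial eta squared with noncentral-F confidence intervals,
    Cronbach's alpha, and Morey-adjusted within-subject intervals), and a
    seeded synthetic-data generator that emits template-pool text whose
    category membership is known by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
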
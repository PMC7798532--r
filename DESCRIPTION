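Package: agenarr
Title: Diachronic Analysis of Aging Narratives from Windowed Collocates
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for measuring how narratives about older adults evolve
    across decades of text. Extracts windowed collocates around a lexicon of
    "older adult" synonyms from a decade- and genre-tagged corpus, filters them
    by a Mutual Information threshold, scores them against multi-rater rating
    lexicons on six dimensions (sentiment, status, warmth, competence,
    medicalization, ostracism), aggregates a frequency-weighted Cumulative
    Aging Narrative Score (CANS) per decade, and fits polynomial trends,
    per-genre per-century topic models (collapsed-Gibbs LDA), and a linear
    mixed model of sociological predictors with decade as a random factor.
    Includes a synthetic corpus generator with planted sentiment drift, planted
    topics, and simulated raters, providing analytic ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
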
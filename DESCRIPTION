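Package: elorank
Title: Elo-Based Rating and Ranking of Items from Pairwise-Comparison Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-judgement surveys in which respondents
    answer forced-choice pairwise comparisons between items. Pooled win/loss
    outcomes are converted into Elo ratings averaged over many randomized
    processing sequences (mElo), min-max normalized to the unit interval
    (n.mElo), and ranked. The package also provides survey design helpers
    (full pair bank, randomized question assignment, triplet-based reliability
    tests), measurement-quality metrics (running consistency indices,
    symmetry, triplet transitivity, test-retest stability, consensus rates,
    content validity indices), simulated random-response null distributions
    with one-sample tests, rater-count plateau curves for sample-size
    estimation, bootstrap confidence intervals and respondent-level
    permutation tests for between-group differences, and a synthetic
    respondent generator with a latent-importance choice model for validation
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
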
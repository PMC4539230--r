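Package: sexdisc
Title: Analysis and Simulation of Sexual Delay Discounting Task Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing behavioral cohorts that completed the
    Sexual Discounting Task (SDT) and a hypothetical monetary delay
    discounting task (DDT). Computes trapezoidal area under the curve
    (AUC) from visual-analog-scale indifference points, compares AUC
    distributions between scenario groups with tie-corrected Wilcoxon
    rank-sum Z tests, relates discounting to questionnaire measures of
    risky sexual behavior via Spearman correlations, and tests for
    differences in correlation strength between independent groups with
    a label-permutation test (C++ resampling engine). A Gaussian-copula
    cohort simulator generates synthetic participants with realistic AUC
    point masses, scenario effects, and rank-correlated questionnaire
    totals, so the full pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
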
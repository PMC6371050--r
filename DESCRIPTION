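Package: mateperm
Title: Permutation Tests and Relocation Effect Sizes for Mate-Choice Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how consistently individuals choose
    long-term partners with similar characteristics. Implements a
    within-respondent consistency index (the population mean of average
    absolute pairwise differences among a respondent's partners), a
    partner-reshuffling permutation test of that index, stepwise-randomization
    effect sizes expressed as the proportion of partners that must be
    relocated between respondents, residual and shared effect sizes between
    trait pairs with a proportional apportionment of higher-order overlaps
    into a maximal cumulative effect size, mixed-model intraclass correlation
    and double-entry pairwise correlation as companion consistency measures,
    and permutation and mixed-model contrasts between partners who did and
    did not father a respondent's children. A synthetic-cohort generator with
    controllable respondent-level clustering supports calibration and
    parameter-recovery studies without access to questionnaire data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
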
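Package: wellcount
Title: Dual-Cutoff Counting Analysis of Multi-Dimensional Wellbeing Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-dimensional wellbeing and ill-being measurement
    from respondent-level survey data using the Alkire-Foster dual-cutoff
    counting methodology. Recodes raw survey answers into binary sufficiency
    indicators via a declarative codebook, applies a two-thirds rule within
    and across domains to classify respondents as having maintained overall
    wellbeing, and computes the deprivation headcount, intensity, and
    adjusted headcount together with censored per-domain deprivation shares.
    Includes subgroup decompositions with gap statistics, a binomial logistic
    model of wellbeing maintenance with Nagelkerke pseudo R-squared and
    classification accuracy, a margin-of-error calculator for sample
    representativeness, and a calibrated synthetic survey generator so the
    full pipeline is testable without access to raw survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
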
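Package: boneagecal
Title: Population-Adapted Bone Age Scales by Median Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing population-adapted bone age scales from
    cross-sectional cohorts of rated hand radiographs. Builds BA - CA
    (bone age minus chronological age) reference curves in one-year age
    bins, calibrates Greulich-Pyle bone age and Tanner-Whitehouse Sum
    Maturity Scores to a target population by tabulating the median
    maturity measure against chronological age, monotonizing it with
    isotonic regression and inverting it, and quantifies rater agreement
    with Bland-Altman statistics. Ships the published BX-China05
    correction table and TW-China05 SMS anchor table for direct
    application to new ratings, and includes a synthetic-cohort
    generator emulating an anniversary-sampled multi-city study design
    so that every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
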
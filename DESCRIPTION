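Package: vitDintake
Title: Vitamin D Vitamers in Food and Population Dietary Intake Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with vitamin D vitamer composition of foods
    (vitamin D3, vitamin D2, 25-hydroxyvitamin D3 and 25-hydroxyvitamin D2,
    in micrograms per 100 g edible portion) and for estimating population
    dietary intake of vitamin D3 and 25-hydroxyvitamin D3 from meal-slotted
    food diaries. Handles left-censored (below limit of quantification)
    measurements with 50%-of-LOQ substitution, composite-food derivation
    (mass-weighted mixtures, part aggregation, yolk-to-whole-egg
    conversion, fat-based prediction), recipe decomposition with
    market-share variant weighting, scenario substitution of composition
    tables, censoring-aware summary statistics, one- and two-factor ANOVA
    (including reconstruction from group means, standard deviations and
    sample sizes) with Tukey honest-significant-difference comparisons,
    and a synthetic 7-day diary generator with closed-form ground-truth
    intake for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
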
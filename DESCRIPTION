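Package: blindval
Title: Blinded Reader-Study Design and Reliability Analysis for
    Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running blinded ("three-blind") validation studies
    of image segmentation: build shuffled, anonymised presentation
    schedules with covert duplicate injection and a sealed provenance map;
    capture validator judgments through a review-loop contract; and compute
    the full reliability analysis, including Dice similarity summaries with
    Student-t intervals, agreement breakdowns, concordance-stratified Dice,
    intra-observer confusion matrices with Cohen's kappa and Wilson score
    intervals, order-of-appearance effects, and annotation-session
    analytics. A synthetic cohort generator with a stochastic validator
    model makes the whole pipeline testable end to end without any real
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
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
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
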
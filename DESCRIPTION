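Package: hijackr
Title: Detecting Genes Deregulated by Structural Variants that Disrupt
    Promoter Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative screen for cis-regulatory disruption
    ("enhancer hijacking") in cancer cohorts. Structural-variant
    breakpoints are flanked and intersected with a promoter-capture Hi-C
    interactome; affected genes are tested for per-donor expression
    outliers in interquartile-range units after median-of-ratios count
    normalization; recurrently deregulated genes sharing a disrupted
    interaction anchor become candidates; candidates are screened for
    overall-survival differences by median-split log-rank tests with
    Benjamini-Hochberg correction. A cohort-concordance stage compares
    extreme-decile donor groups of a focal gene against externally
    supplied gene sets with a Mann-Whitney shift test. A negative-
    binomial synthetic-cohort generator with planted ground truth makes
    every stage testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
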
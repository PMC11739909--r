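Package: trialscan
Title: Integrity Screening of Baseline Categorical Data in Randomized
    Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to screen published randomized controlled trials for
    inconsistencies in their baseline categorical data. Checks that
    level-frequency sums agree with randomized group sizes, recalculates
    reported baseline p-values with a battery of contingency-table tests
    (Pearson and continuity-corrected chi-square, exact and Monte-Carlo
    Fisher, mid-p, G-test, one-way goodness-of-fit) under standard
    sparse-data rules, matches reported against recalculated p-values at
    the printed decimal precision, compares observed between-group
    frequency-difference and p-value distributions with re-randomization
    null distributions, combines a trial's baseline p-values into a
    studywise p-value by the Stouffer method, checks standardized
    submission baseline tables, and generates synthetic trial datasets
    with controlled anomaly injection for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    readxl,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
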
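Package: scorecp
Title: Pseudo-Score Changepoint Tests and Power Analysis for Segmented
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests for the existence of a single changepoint (breakpoint)
    in jump-point and segmented (broken-line) regression models using the
    pseudo-score statistic, whose null and alternative distributions are
    standard normal.  Includes the classical benchmark tests for a change
    point: the maximum two-sample t statistic for a mean shift in normal
    sequences and the trimmed likelihood-ratio statistic for ability
    shifts in binary Rasch-model item-response sequences.  Provides
    analytic power computation and sample-size planning for the segmented
    alternative, post-experimental power with a simulation-based
    confidence interval, Monte-Carlo study runners for type-I error and
    power, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
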
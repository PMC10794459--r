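Package: visagree
Title: Web Versus Lab Agreement Analysis for Forced-Choice Orientation Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and validating visual function remotely: a
    two-alternative forced-choice (2AFC) orientation-identification task model
    with method-of-constant-stimuli scheduling and Gabor stimulus geometry, a
    synthetic observer that generates Bernoulli trial responses from a logistic
    psychometric function with a controllable web/lab reliability structure,
    least-squares psychometric threshold estimation (75% correct criterion),
    and the full group-level and agreement analysis pipeline: repeated-measures
    ANOVA with Mauchly/Greenhouse-Geisser sphericity handling, Bonferroni
    pairwise comparisons with effect sizes, intraclass correlation ICC(2,1)
    with F-based confidence intervals, Bland-Altman limits of agreement on the
    log (ratio) scale, median absolute ratio error metrics, and ICC-based
    sample-size planning for reliability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    minpack.lm,
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
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
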
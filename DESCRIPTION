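Package: dietval
Title: Validation of Dietary Assessment Tools Against Doubly Labelled Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end validation analysis of dietary-assessment tools
    against the doubly labelled water (DLW) reference method. Implements the
    two-point DLW protocol (elimination constants, isotope dilution spaces,
    body composition, quality-control ratios, CO2 production by the Speakman
    equation, energy expenditure by the Weir equation), aggregation of
    eating-occasion records to daily energy intake with within-subject
    coefficients of variation, Goldberg cut-off misreporting classification
    with the Black S factor, an agreement-statistics suite (Bland-Altman
    limits of agreement with confidence intervals, normality-gated paired
    tests, Pearson correlation with Bonferroni adjustment, intraclass
    correlation by random-intercept model, over/under-estimation summaries),
    a nine-step validity benchmark report, and a synthetic-cohort generator
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
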
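Package: lipidtrial
Title: Tailored Cholesterol-Advice Engine and Randomized-Trial Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for guideline-driven tailored cholesterol management advice
    and for the design, simulation and intention-to-treat analysis of a
    two-arm randomized trial of such advice. Provides a deterministic
    rule engine that classifies statin eligibility and lipid-target
    attainment against a configurable guideline rule set and generates
    per-participant advice plans and plain-text letters; a synthetic
    cohort generator calibrated to published baseline prevalences and
    arm-specific outcome probabilities, including realistic lipid
    missingness and incomplete follow-up; and the trial statistics:
    unpooled Wald confidence intervals for differences in proportions,
    the 2x2 Pearson chi-square test without continuity correction,
    Welch t contrasts for continuous outcomes, and two-proportion power
    and sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
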
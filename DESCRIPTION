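Package: u5mcompare
Title: Age Patterns of Under-5 Mortality from Surveillance and Birth Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and comparing age patterns of under-5
    mortality across data sources. Implements direct estimation of neonatal,
    postneonatal, infant, child, and under-5 probabilities of dying from
    demographic-surveillance residency episodes (Lexis age-period exposure
    splitting with piecewise-constant hazards) and from retrospective full
    birth histories; a two-dimensional log-quadratic model of the under-5
    age pattern (level plus shape) with fitting, prediction, level solving,
    and indirect estimation curves; age-pattern ratio analytics with
    nonparametric median comparisons; region-matched relative-difference
    comparison of surveillance and survey estimates; data-quality metrics
    (day-of-death digit preference, birth-history quality composite); and
    regression of estimate discrepancies on fieldwork, context, and quality
    covariates. A microsimulation generator produces surveillance
    populations and survey birth histories with known true mortality and
    configurable reporting-error processes.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
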
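Package: seamlessDx
Title: Seamless Diagnostic Accuracy Study Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planning, analysis and simulation tools for the seamless
    diagnostic accuracy study design, a two-stage design that embeds a
    case-enriched, case-control-like interim analysis with futility
    stopping inside an ongoing population-based cohort study of a single
    index test. Provides Wilson-score confidence intervals and the
    intersection-union confirmatory test for the co-primary sensitivity
    and specificity endpoints, interim analysis-population composition
    arithmetic, a single-trial simulation and analysis engine with an
    exact enumeration oracle for the stopping probability, and a scenario
    sweep that computes Monte Carlo operating characteristics (stopping
    probability, conditional relative bias, coverage, power, type I
    error) over a factorial grid of designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
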
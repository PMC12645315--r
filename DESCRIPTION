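Package: selreg
Title: Selection Gradients on Reproductive Timing from Population-Register Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for register-based phenotypic selection analysis on human
    reproductive timing. Reads register-style reproductive histories (one row
    per individual: sex, birth year, educational attainment, offspring count,
    first and last child birth years), derives ages at first and last birth
    and average interbirth intervals, computes relative lifetime reproductive
    success within sex-by-birth-year cohorts, and estimates standardized
    Lande-Arnold linear (beta) and quadratic (gamma) selection gradients with
    confidence intervals, stratified by sex, educational attainment, and birth
    cohort. Includes cohort-trend summaries, a synthetic population-register
    generator with configurable true selection parameters and
    education-dependent father under-registration for validation by parameter
    recovery, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
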
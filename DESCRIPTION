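Package: deatonuv
Title: Price and Expenditure Elasticities from Unit Values by Deaton's Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates conditional price and expenditure elasticities of demand
    from clustered household expenditure surveys using Deaton's unit-value
    method: unit-value extraction and CPI deflation, a one-way ANOVA test of
    spatial price variation, within-cluster fixed-effects regressions of log
    unit value and budget share (linear-approximate AIDS), cluster residual
    averaging, a measurement-error-corrected between-cluster slope, and the
    quality-shading correction formulas that recover the price and expenditure
    elasticities. Includes a synthetic clustered-survey generator with known
    ground truth, cluster bootstrap inference, and an SD-based unit-value
    trimming robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
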
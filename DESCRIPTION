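Package: prevcea
Title: Trial-Based Cost-Effectiveness Analysis of Indicated Depression
    Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for trial-based health-economic evaluation of indicated
    depression prevention: synthetic two-arm prevention-trial cohorts with
    zero-inflated resource-use panels and correlated utility trajectories,
    costing from resource-use questionnaires under societal and health-care
    perspectives with human-capital valuation of productivity losses,
    depression-free-year and QALY area-under-the-curve outcome construction,
    conditional-mean regression imputation with predictor screening,
    Kaplan-Meier restricted mean survival and Cox proportional-hazards
    comparison, and bootstrapped seemingly-unrelated-regression estimation of
    incremental cost-effectiveness ratios with cost-effectiveness planes and
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
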
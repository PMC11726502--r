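Package: ssbcea
Title: Microsimulation Cost-Effectiveness Analysis of a Sugar-Sweetened
    Beverage Excise Tax
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level state-transition (Markov) microsimulation of a
    1-cent-per-ounce sugar-sweetened beverage excise tax for a cohort of
    Californian adults. Generates a synthetic baseline population calibrated
    to survey weight moments, advances individuals through annual cycles of
    weight change, BMI reclassification, and transitions among obesity-related
    disease states (diabetes, stroke, myocardial infarction, end-stage renal
    disease) with tunnel states for acute event years, accrues discounted
    costs and quality-adjusted life-years, and compares the tax against a
    status-quo arm from health-care and government perspectives (ICER, net
    monetary benefit, cost-effectiveness acceptability curves). Parameter
    uncertainty is propagated by probabilistic sensitivity analysis with
    moment-matched gamma, beta, log-normal and normal distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
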
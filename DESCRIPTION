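Package: wastingMarkov
Title: Markov Cohort Estimation of Child Wasting Incidence and Caseload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An eight-state discrete-time Markov cohort model of child
    wasting (acute malnutrition) progression and community-based treatment
    (TSFP, OTP, TFC). Unknown monthly incidence transition probabilities
    are back-calculated by bisection calibration against cross-sectional
    SMART survey prevalence targets, and converted to mean episode
    durations and incidence correction factors (k = 12 / duration) used
    for annual treatment caseload estimation. Includes one-way
    deterministic sensitivity analysis over 50-150 percent parameter
    ranges, a packaged configuration for the Lahj governorate of Yemen,
    and a seeded synthetic program-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
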
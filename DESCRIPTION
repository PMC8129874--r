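Package: placewear
Title: Sensor Placement Evaluation for Wearable Activity Recognition and
    Energy Expenditure Estimation
Version: 0.1.0
Authors@R:
    person("Placewear", "Developers", email = "placewear@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how the number and body placement of wearable
    triaxial accelerometers affect physical-activity recognition and energy
    expenditure estimation. Simulates seeded cohorts of older adults wearing
    five accelerometers (ankle, upper arm, hip, thigh, wrist) during scripted
    activities together with breath-by-breath oxygen-uptake traces; extracts
    fifteen time- and frequency-domain features from contiguous 16-second
    windows; converts VO2 to metabolic equivalents (METs) via steady-state
    plateau extraction; and runs participant-exclusive nested cross-validation
    with random forests over all 31 placement combinations to rank placements
    by balanced accuracy, accuracy and RMSE, including a most-efficient
    combination selection rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
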
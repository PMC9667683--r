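Package: modesense
Title: Minute-Level Transport Mode Detection from GPS, Accelerometer and
    Heart Rate Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the transport mode used during every minute
    of a multi-sensor mobility follow-up. Provides a seeded simulator for
    synthetic cohorts (trip timetables plus GPS fix, 5-second accelerometer
    epoch and RR-interval streams), minute-level feature engineering (GPS
    quality filtering and summary statistics, activity-count energy
    expenditure, heart-rate variability), 100-tree random-forest prediction
    with leave-one-participant-out cross-validation, class-prevalence vote
    cutoff correction, moving-majority homogenization of predicted mode
    sequences, and prediction-rate reporting with cross-participant
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    ranger,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
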
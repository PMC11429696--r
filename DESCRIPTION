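Package: gazepoll
Title: Gaze-Bias Election Prediction and Facial Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for converting preferential-looking eye-tracking data into
    two-alternative election "votes" and relating landmark-based facial
    masculinity metrics to vote share. Ingests fixation-level gaze records,
    election metadata, and facial landmark tables; scores per-trial gaze bias
    under count, dwell-time, and first-fixation rules; computes normalized
    facial width metrics (jaw prominence, facial width-to-height ratio, lower
    face prominence) with multi-rater aggregation; and runs the downstream
    correlation, partial-correlation, and joint linear-model analyses. A
    fully parameterized synthetic-data generator with an analytic accuracy
    oracle supports calibration, parameter recovery, and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
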
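Package: fallsense
Title: Chest-Worn IMU Fall Recognition and Verification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Threshold-based fall detection for a chest-worn inertial
    measurement unit with a barometric altimeter. Provides gradient-descent
    (Madgwick) orientation fusion, Kalman-filtered relative altitude, a Mealy
    finite-state machine for posture and behavior tracking, a conjunctive
    resultant-acceleration/pressure-change fall rule with fall-direction and
    impact-magnitude classification, two-stage fall-alert verification with a
    cancellation window, a seeded synthetic sensor-trace simulator emulating
    standard fall protocols and activities of daily living, and evaluation
    utilities (sensitivity, specificity, accuracy per fall category).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
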
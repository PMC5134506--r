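Package: armspot
Title: Gesture Spotting and Counting of Overhead Arm Motions from a
    Wearable Inertial Measurement Unit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking and counting overhead arm motions (baseball
    throws and volleyball serves) from a single upper-arm 9-axis inertial
    measurement unit sampled at 50 Hz. Provides quaternion attitude-and-heading
    (AHRS) sensor fusion with arm-elevation estimation, debounced event-count
    histograms of elevation and angular-rate magnitude, a two-stage real-time
    gesture spotter (threshold rule plus fixed-window segment extraction), an
    81-value time/frequency feature vector with forward sequential feature
    selection, a bagged decision-tree classifier with posterior-score
    null-class rejection, Bland-Altman count-agreement statistics, and a
    ground-truthed synthetic session simulator covering throws, serves, seven
    resisted shoulder exercises, and rest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
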
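Package: vo2pipe
Title: Predicting VO2max from Submaximal Treadmill Running with Wearable Sensors
Version: 0.1.0
Authors@R:
    person("vo2pipe", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting maximal oxygen uptake (VO2max)
    from submaximal treadmill running using heart-rate and body-worn
    accelerometer data. Implements raw-signal preprocessing (30 s rolling
    VO2max, 10 s heart-rate binning with 7-point median smoothing, 50 Hz
    zero-phase low-pass filtering, Moe-Nilssen tilt correction), a 490-column
    candidate feature catalogue over protocol stages, ground-contact-time
    estimation from vertical lower-back acceleration via zero crossings,
    a random-intercept linear mixed model estimated by REML, greedy forward
    feature selection scored by inner leave-one-subject-out adjusted explained
    variance, nested leave-one-subject-out evaluation with five error metrics,
    and a calibrated synthetic treadmill-session generator so that the whole
    pipeline is testable without access to laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
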
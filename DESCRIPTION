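Package: shakestep
Title: Shake-Service Step Counting: Calibration and Validation of a
    Delta-Threshold Accelerometer Event Detector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts steps from pocket-worn smartphone tri-axial
    accelerometry with a "shake-service" event detector: an
    acceleration-delta threshold (sensitivity) combined with a refractory
    window (refresh time). Provides a synthetic over-ground gait
    simulator with exact ground-truth step counts, a grid-search
    calibration procedure that selects per-speed detector settings by
    minimising the absolute step-count difference, a fixed-parameter
    baseline counter standing in for non-tunable native pedometers, and
    a validation stage that contrasts counting methods per platform,
    speed and distance with cluster-adjusted negative binomial
    regression fitted by generalized estimating equations (exchangeable
    working correlation, robust standard errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
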
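Package: myoreach
Title: Myoelectric Pattern-Recognition Control of Robotic Arm Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of real-time myoelectric pattern-recognition
    control of vertical arm support for reaching after stroke. Provides surface-EMG
    conditioning (20-350 Hz band pass with a 50-70 Hz stop band), sliding-window
    Hudgins time-domain plus 6th-order autoregressive feature extraction, a
    three-class (abduction / adduction / no movement) minimum-Mahalanobis-distance
    classifier with class-wise proportional control, incremental vertical position
    and force support controllers, a one-degree-of-freedom admittance-robot
    simulator with virtual rigid surfaces, a synthetic stroke-subject EMG generator
    with abnormal-synergy coupling, and an evaluation pipeline for reach-excursion
    metrics, normalized EMG effort, paired one-sided t-tests, and
    unrelated-movement confusion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
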
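Package: tugfall
Title: Fall-Risk Discrimination from Instrumented Timed Up and Go Tests
Version: 0.1.0
Authors@R: person("TUG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates, segments and analyses instrumented Timed Up and Go
    (TUG) recordings for fall-risk screening in community-dwelling older
    adults. A synthetic-data module generates paired lumbar-IMU and
    depth-camera skeleton streams with ground-truth phase boundaries and
    two-cohort gait contrasts; a segmentation module partitions the TUG into
    its five subtasks from yaw and pitch angular velocity; a feature module
    extracts a 142-parameter vector (temporal, acceleration, angular
    velocity, key-point and demographic parameters); and a statistics module
    runs normality-gated two-group tests, Cohen's d effect-size screening,
    logistic regression and a sensor-ablation AUC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
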
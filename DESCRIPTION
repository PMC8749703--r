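Package: turnkin
Title: Kinematic Analysis of 360-Degree Turning from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing on-spot 360-degree turning recorded with a
    four-sensor inertial measurement unit (IMU) configuration (sternum, sacrum,
    and both shanks). Provides a seedable synthetic-trial generator with known
    ground truth, zero-phase Butterworth preprocessing, temporal segmentation of
    the leading shank into gait cycles (mid-swing, toe-off, heel-strike), spatial
    segmentation of the trailing shank's cumulative rotation into equal angular
    partitions, extraction of angular-velocity and range-of-motion parameters per
    body segment, and group-comparison tables (unpaired t-tests and percent
    differences) contrasting stroke survivors with healthy individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
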
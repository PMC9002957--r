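Package: gaitkit
Title: Markerless Multi-Camera Gait Kinematics with Constrained Skeletal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A markerless motion-capture analysis pipeline for multi-camera
    video setups: confidence-weighted robust triangulation of per-camera 2D
    joint keypoints (Direct Linear Transform), zero-lag Butterworth filtering,
    coordinate-based gait event detection, measurement-based scaling and
    constrained inverse kinematics on an articulated full-body skeletal model,
    and concurrent-validation statistics (inter-protocol coefficient of
    multiple correlation, range-of-motion error tests, Bland-Altman limits of
    agreement) for comparing joint-angle waveforms between two measurement
    systems. Ships a virtual-camera gait simulator with known ground truth so
    every pipeline stage can be exercised and validated without capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
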
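Package: gaitplanes
Title: Body-Axis Plane Projection and Tolerance-Ellipse Gait Metrics for
    Markerless Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative gait analysis from markerless 3D pose-estimation
    keypoint time series recorded during circular walking. Builds per-frame
    body-centric coordinate frames from trunk keypoints, projects all
    keypoints onto body-relative sagittal, coronal and axial planes with
    leg-length and upper-body-length normalization, fits 75% tolerance
    ellipses to the projected point clouds, and derives upper- and
    lower-limb gait parameters: joint angle ranges, ellipse areas, and
    lateral outward shifts that quantify arm swing and wide-based gait.
    Includes a synthetic circular-walking generator with disease-archetype
    presets (Hakim's disease / idiopathic normal-pressure hydrocephalus,
    Parkinson's disease, cervical myelopathy, healthy) and cohort-level
    Pearson correlation reporting with Fisher-z confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
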
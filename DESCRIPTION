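Package: gaitvision
Title: Markerless Gait Analysis and Fall-Risk Modelling from 2D Pose
    Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating spatiotemporal gait variables of older
    adults from 2D human-pose keypoint sequences recorded by a single
    hallway camera. Reads OpenPose-style per-frame keypoint JSON, selects
    the participant track among multiple detected people, gates low
    confidence keypoints with linear imputation, low-pass filters
    trajectories, detects foot strikes from ankle vertical velocity, and
    computes seven hip-span-normalized gait variables per walking bout
    (cadence, step-time symmetry index, step-time and step-width
    variability, average step width, and average/minimum estimated margin
    of stability from an extrapolated centre of mass). Includes PCKh
    keypoint-accuracy verification against manual annotations, baseline
    averaging over an enrollment window, and cohort-level association
    models: univariate linear regression of gait variables on mobility
    scores and univariate/multivariate Poisson regression of prospective
    fall counts with an exposure offset. A synthetic-data module
    simulates walking bouts and cohorts with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
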
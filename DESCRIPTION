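Package: quailkin
Title: Biplanar Gait Kinematics of Birds Negotiating Vertical Steps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for three-dimensional hindlimb and pelvic
    kinematics of small ground birds recorded with a biplanar (two-view) rig:
    semi-automatic landmark localization with per-landmark linear epsilon-support
    vector regressors, 11-coefficient direct linear transformation (DLT)
    calibration and two-view triangulation, anatomical coordinate frames with
    Cardan z-x-y joint angles, effective-leg (spring-loaded) gait variables,
    stride segmentation with 100-point time normalization, and the associated
    statistical layer (Levene-gated TukeyHSD or Games-Howell post hoc tests and
    repeated-measures ANOVA). A forward-kinematic gait generator reproduces
    published level and step-negotiation walking of the common quail so the whole
    pipeline can be exercised and validated without fluoroscopy recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    car,
    optparse
Config/testthat/edition: 3
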
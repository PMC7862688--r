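Package: reachcv
Title: Reach-to-Grasp Kinematics, Identity Confounding and
    Cross-Validation Schemes for Clinical Movement Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing prospective reach-to-grasp kinematics in
    clinical group-classification studies. Extracts the classic five-variable
    kinematic profile (wrist velocity, acceleration, jerk, grip aperture,
    wrist height, each time-normalized to deciles of movement duration) from
    3D hand-marker trajectories; simulates marker-level reach-to-grasp
    datasets with hierarchical structure (subject signatures, diagnostic-group
    effects on velocity-landmark timing, intention effects); and implements
    record-wise, subject-wise and hybrid cross-validation with nested
    hyper-parameter tuning, subject-level posterior aggregation, and
    subject-block permutation nulls that diagnose identity confounding in
    repeated-measures classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    ranger,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
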
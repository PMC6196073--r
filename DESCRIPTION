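Package: oppkin
Title: Kinematics of Thumb-Finger Opposition Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for finger-thumb opposition kinematics recorded
    with multi-sensor motion tracking. Transforms raw 3D digit trajectories to a
    wrist-referenced frame, applies zero-lag Butterworth smoothing and
    five-point-stencil differentiation, segments the onward movement with a
    relative velocity threshold, and computes per-trial displacement ratios
    (with Fisher z-transform) and spectral-arc-length movement smoothness.
    Includes repeated-measures ANOVA with Huynh-Feldt sphericity adjustment,
    Bonferroni post-hoc comparisons, and a synthetic-session generator that
    emulates the experimental protocol (8 participants x 12 tasks x 15 trials
    of paired minimum-jerk opposition movements) with recorded ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
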
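Package: iapsync
Title: Intrapersonal Synchrony Analysis of Gaze-Gesture Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify intrapersonal synchrony (IaPS) between
    communicative gaze shifts and pointing gestures from high-rate
    eye-tracking data. Includes a velocity-threshold gaze-event parser,
    a rule-based selector for communicative gaze shifts with ordered
    exclusion criteria, gaze-gesture delay metrics and channel-use
    coding, color-blob fingertip tracking for gesture kinematics from
    video frames, a synthetic two-group cohort generator with full
    ground truth, and a likelihood-ratio model-comparison interface for
    linear and generalized linear mixed models with Satterthwaite
    p-values, convergence fallback and complete-separation detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
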
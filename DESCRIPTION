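Package: semghier
Title: Hierarchical Surface-EMG Decoding of Hand Gestures and Grasp Force Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous pattern-recognition decoding of seven hand/wrist
    gestures and, for the two grasping gestures (Spherical and Tip), three
    grasp-force levels from multi-channel enveloped surface-EMG signals.
    A finite state machine coordinates one always-active gesture classifier
    and two hierarchically activated force classifiers, each realised both as
    a non-linear logistic regression (polynomial feature expansion trained by
    resilient backpropagation) on scaled raw envelope samples and as a
    one-vs-all linear discriminant analysis on sliding-window time-domain
    features (MAV, RMS, SSC, WL, variance). Includes a synthetic-session
    generator emulating the acquisition protocol (six repetitions of each
    gesture held for 2 s at 1 kHz, with FSR-derived grasp-force bands at
    30/60/90% +/- 15 percentage points of maximum force), stratified
    three-way/two-way data splits with a downsampling-derived generalization
    set, per-class F1/accuracy/confusion-matrix evaluation, and a paired
    Wilcoxon signed-rank comparison of the two algorithm families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
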
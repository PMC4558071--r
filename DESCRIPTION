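Package: pupilsweep
Title: Pupillometry and Saccade Kinematics Pipeline for Intrasaccadic
    Perception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse pupillometric evidence for intrasaccadic
    perception: preprocessing of 1000 Hz monocular gaze and pupil-area
    recordings (Hanning position smoothing, velocity estimation, saccade
    landmark detection, cubic-spline blink reconstruction, epoching to the
    mid-saccade point with baseline normalization), trial-exclusion rules,
    velocity-matched calibration of polarity-reversing flicker gratings, a
    retinal-stabilization model of the intrasaccadic percept, sample-wise
    linear mixed-effects time-course analysis with a consecutive-samples
    reliability rule, and a synthetic-experiment generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
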
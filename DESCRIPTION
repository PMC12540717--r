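Package: semgrec
Title: Surface-EMG Hand-Gesture Recognition with Success-History
    Adaptive Differential-Evolution Hyperparameter Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for myoelectric hand-gesture recognition from
    multi-channel surface electromyography (sEMG): two-stage IIR
    denoising (50 Hz notch followed by a 4th-order 10-500 Hz Butterworth
    band-pass), overlapping-window segmentation, extraction of 17
    time- and frequency-domain features per channel, classification with
    an extremely-randomized-trees backend behind a named registry, and
    hyperparameter optimization by a from-scratch L-SHADE (success-history
    adaptation differential evolution with linear population size
    reduction) engine over a mixed integer/categorical search space.
    Includes a seeded synthetic sEMG generator, temporal train/test
    splitting, cross-session evaluation, paired t-tests, and a
    declarative experiment runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
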
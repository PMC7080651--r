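Package: prealpha
Title: Single-Trial Prestimulus Alpha Power and Response-Time Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of the coupling between prestimulus
    occipital alpha oscillations (7-14 Hz) and response time in a flanker
    task, contrasting healthy older adults with mild cognitive impairment.
    Provides a synthetic-cohort generator with analytically controlled
    alpha-RT rank correlation (Gaussian copula), EEG preprocessing (average
    reference, zero-phase FIR band-pass, baseline correction, trial
    exclusion), single-trial spectrograms via a windowed Fourier transform
    with Hanning taper and zero padding, fast/slow median-split and
    within-subject Spearman/Fisher-z coupling statistics, mixed-design
    ANOVAs with Greenhouse-Geisser correction, and a nested cross-validated
    RBF-SVM protocol with exhaustive feature-subset selection for group
    classification and neuropsychological-score regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
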
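Package: evombn
Title: Evolving Multi-Branch Networks for 12-Lead ECG Myocardial
    Infarction Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic-algorithm architecture search over multi-branch
    one-dimensional residual convolutional networks for myocardial
    infarction detection and localization from 12-lead electrocardiograms.
    Provides the full beat-level preprocessing chain (resampling to 250 Hz,
    Daubechies-6 wavelet denoising, R-peak detection, 256-sample beat
    segmentation, per-lead z-scoring), per-lead residual branch networks
    with 17 convolutional layers trained by stochastic gradient descent, a
    lead squeeze-and-excitation (LSE) attention head, a fixed-length
    integer genome encoding of multi-branch architectures with crossover,
    mutation, elitist selection and early stopping, inter-patient
    cross-validation, architecture transfer, and a synthetic 12-lead ECG
    generator with location-specific lead perturbations so that every
    stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
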
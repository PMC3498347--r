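Package: rumblecam
Title: Acoustic-Camera Localization and Classification of Nasal and Oral
    Elephant Rumbles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses low-frequency elephant rumble
    vocalizations recorded by a star-shaped microphone array. Provides
    delay-and-sum beamforming with effective sound-pressure-level acoustic
    maps for allocating calls to nasal (trunk-tip) or oral (mouth) emission,
    a source-filter synthesizer producing calibrated rumbles with
    tube-model formants, pitch/duration/formant measurement with vocal
    tract length estimation from formant spacing, and LPC spectral
    descriptors with linear classifiers (LDA, linear SVM,
    nearest-neighbour) under a split plus cross-validation evaluation
    protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
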
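Package: eegsa
Title: EEG Band-Ratio Identification of At-Risk Situation Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying low situation-awareness cognitive states
    from multi-region EEG recordings. Provides a seeded synthetic EEG cohort
    generator with planted group-level band-ratio differences, DFT/PSD
    spectral estimation with band-power ratio metrics and sliding-window
    feature extraction, permutation screening of group differences with
    Welch's t, random-forest out-of-bag importance ranking with backward
    feature elimination, principal-component feature combination with
    composite weighting, a PCA-fused convolutional classifier trained by
    stochastic gradient descent, and ROC/AUC evaluation harnesses comparing
    random-forest, convolutional, and hybrid classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
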
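Package: eegdwt
Title: Wavelet Sub-Band Entropy Features and Classification for Parkinson's
    Disease EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete wavelet transform (DWT) based feature extraction and
    classification of resting-state EEG for discriminating Parkinson's disease
    from healthy controls. Implements 4-level db4 decomposition with
    per-coefficient signal reconstruction, eight signal complexity measures
    (energy, log band power, threshold, norm, sure, log-energy and Shannon
    entropies, and a transformation-Shannon entropy based on an image-style
    intensity mapping), five classifiers with fixed literature parameters,
    repeated stratified k-fold and leave-one-subject-out cross-validation,
    greedy forward-addition channel selection, a seeded synthetic EEG cohort
    generator, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    class,
    MASS,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
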
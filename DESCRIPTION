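Package: prpdecode
Title: Phoneme-Related Potentials, Convolutional Decoding and Encoding
    Models for Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the cortical distinctiveness of phoneme
    representations in continuous-speech EEG. Implements phoneme-related
    potential (PRP) extraction with frequency-based retention and
    instance-cap balancing, a compact convolutional phoneme classifier
    with cross-validated accuracy and prediction entropy, reference-based
    attribution of classifier decisions to electrodes and time with
    dispersion and peak-latency statistics, representational similarity
    analysis against binary phonetic-feature models with forward
    electrode selection and permutation tests, multivariate temporal
    response functions estimated by L1 coordinate boosting with
    unique-variance partitioning, cluster-mass permutation statistics,
    and a synthetic-EEG cohort generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    ape,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
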
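Package: popdecode
Title: Population Decoding of Calcium-Imaging Responses in Mouse Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for linear population decoding of two-photon
    calcium-imaging recordings: delta-F-over-F preprocessing with a sliding
    1-s baseline, stimulus-epoch and drifting-grating trial segmentation into
    z-scored population feature vectors, linear support vector machine and
    multinomial logistic regression decoders with nested cross-validation and
    balanced training subsamples, accuracy-versus-population-size scaling
    curves with a constrained generalized-logistic fit, trial-shuffled
    correlation-blind decoding to quantify the contribution of noise
    correlations, per-neuron orientation and direction selectivity indices,
    and the accompanying multiple-comparison statistics. A synthetic-data
    generator with parameterized tuning curves and a controllable shared-gain
    noise-correlation structure emulates multi-session recordings so that
    every stage is testable without access to experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    nnet,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'popdecode-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'decode.R'
    'io.R'
    'methods.R'
    'pipeline.R'
    'preprocess.R'
    'scaling.R'
    'selectivity.R'
    'simulate.R'
    'stats.R'
    'synergy.R'
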
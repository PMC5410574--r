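Package: cdpMarkov
Title: Markovian Analysis of Spontaneous Cord Dorsum Potential Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the sequential analysis of spontaneous cord dorsum
    potentials (CDPs) recorded from the spinal cord surface. The package
    detects CDP-like events in voltage traces, builds per-segment shape
    dictionaries (PCA denoising plus k-means prototypes), discretizes
    recordings into symbol sequences with explicit pause tokens, tests the
    Markov order of the resulting sequences with chi-squared and
    surrogate-data methods (including exact pair-count-preserving Whittle
    surrogates sampled as uniform Eulerian trails), and identifies the
    functional state that generated a held-out sequence by transition-model
    log-likelihood. A ground-truthed synthetic-data generator emulates the
    statistical structure of multichannel CDP experiments so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    cluster,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'cdpMarkov-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'markov.R'
    'classification.R'
    'detection.R'
    'dictionary.R'
    'pipeline.R'
    'plots.R'
    'symbolization.R'
    'synthetic.R'
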
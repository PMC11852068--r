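Package: nclnet
Title: Coherence Network Dynamics and Decoding for Multichannel LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for event-related functional connectivity in
    multichannel local field potential (LFP) recordings, built around target
    detection experiments in the avian nidopallium caudolaterale. Provides a
    synthetic cohort generator with planted band-specific coupling changes,
    zero-phase Butterworth/notch preprocessing with downsampling and five-band
    decomposition, sliding-window multitaper coherence networks, hypergeometric
    Surprise based threshold selection with percolation diagnostics, average
    node degree and modularity network features, pre/post ANOVA comparisons,
    and decoding of detection state with margin, recurrent and tree classifiers
    under stratified ten-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    igraph,
    e1071,
    rpart,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
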
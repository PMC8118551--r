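Package: threadcrf
Title: Protein Threading with Alignment Conditional Random Fields and
    Predicted Distance Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Template-based protein modelling tools built around a five-state
    pairwise-alignment conditional random field (match, template/query
    insertions, head and tail gaps). Provides Viterbi and maximum expected
    accuracy decoding, exact log-space forward-backward inference,
    maximum-likelihood training of emission scorers (a linear feature scorer
    and a deep residual convolutional scorer), conversion of predicted
    Cbeta-Cbeta distance distributions into DFIRE-referenced potentials,
    an ADMM optimizer for the distance-augmented threading objective,
    alignment refinement inputs, template ranking by a normalized selection
    score, reference-dependent alignment evaluation, and a synthetic toy-fold
    generator so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
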
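Package: emosource
Title: Emotion Decoding from EEG via Sparse Bayesian Source Localization
    and Dynamic Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding emotional state from multichannel EEG by
    working in source space rather than sensor space.  Scalp recordings are
    inverted with a spike-and-slab (Bernoulli-Laplace) Bayesian model sampled
    by a coordinate-wise Gibbs sampler and initialized from the sLORETA
    standardized minimum-norm solution; the recovered sparse source time
    courses are turned into correlation-weighted graphs; and emotional class
    is predicted by a dynamic graph convolutional network whose Chebyshev
    spectral filters operate on an adjacency matrix that is itself learned
    during training.  A self-contained synthetic module simulates lead
    fields, class-conditional sparse cortical activity and noisy sensor
    epochs so the whole pipeline can be exercised and validated without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
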
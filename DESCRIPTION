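Package: neuroTE
Title: Signed Neuronal Connectivity Inference via Local Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An in-silico benchmark for inferring signed (excitatory versus
    inhibitory) synaptic connectivity from calcium-imaging-like recordings.
    Provides a spatially embedded quadratic integrate-and-fire network
    simulator with spike-frequency adaptation and depressing alpha-function
    synapses, a calcium fluorescence forward model with acquisition noise and
    down-sampling, derivative-threshold spike re-detection, a plug-in Transfer
    Entropy estimator decomposed into local excitatory and inhibitory
    components evaluated at configurable bin delays, and ROC-based scoring of
    the inferred matrices against the ground-truth structural network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
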
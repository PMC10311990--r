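Package: silentnet
Title: Stimulation-Mediated Inference of Synaptic Connectivity in Silent
    Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates heterogeneous spiking populations containing silent
    neurons (firing at ~1 spike/min), drives memoryless threshold and leaky
    integrate-and-fire postsynaptic models, and derives synaptic connection
    weights from (presynaptic raster, postsynaptic spike train) pairs with an
    online perceptron learning rule. Provides stimulation protocols that
    transiently elevate random subsets of the population to high firing rates,
    evaluation of weight recovery (RMSE, correlation, connection-type
    classification) and bin-wise spike prediction (sensitivity, precision),
    recurrent circuit construction with reciprocal-connection statistics, a
    surrogate multichannel-recording generator, and coverage/rate scaling
    analyses for large populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
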
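Package: dcmgain
Title: Dynamic Causal Modeling of Attentional Gain in Evoked Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and inverts a hierarchical canonical-microcircuit neural
    mass model of spatial attention in the Posner cueing paradigm. Attention is
    encoded as the gain (inverse self-inhibition) of superficial pyramidal
    populations, modulated top-down by deep-pyramidal afferents. The package
    generates synthetic MEG-style evoked responses from an eight-source visual
    hierarchy, preprocesses trial sets (bandpass, downsample, epoch, robust
    average), fits models to canonical-mode data by variational Laplace, and
    decides where condition-specific gain differences live by free-energy
    Bayesian model comparison and Bayesian model reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
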
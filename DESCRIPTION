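Package: adaptivenodes
Title: Spiking Neural Networks with Adaptive Dendritic Terminals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fixed-step simulation of leaky integrate-and-fire networks in
    which plasticity acts on dendritic terminals (nodes) rather than on
    individual synaptic links. Every link converging on a terminal shares one
    adaptive multiplier, which is updated by a pair-based, signed-exponential
    rule driven by the time lag between sub-threshold stimulations and evoked
    spikes. The package builds feedforward, two-pool and random recurrent
    topologies, generates periodic and Poisson stimulation protocols, and
    provides analysis drivers for terminal-weight dynamics (fixed points,
    fast and slow oscillations), dynamical-attractor censuses, the stationary
    log-normal distribution of effective link weights, spike-pair ordering
    probabilities and the emergent restoring force, including refractory
    period sweeps. A classical adaptive-link mode is included as a baseline.
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
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
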
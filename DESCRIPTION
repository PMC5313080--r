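Package: ca1net
Title: Configurable-Scale Hippocampal CA1 Microcircuit Simulation and
    Theta/Gamma Oscillation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable-scale spiking-network model of the rodent
    hippocampal CA1 region (one pyramidal cell type plus eight interneuron
    classes), with distance-dependent connectivity generated from axonal
    bouton distributions, reduced adaptive exponential integrate-and-fire
    neurons fit to published electrophysiology, double-exponential
    conductance synapses including mixed GABA-A/GABA-B components, Poisson
    and theta-modulated afferent drive, perturbation operators (muting,
    interneuron homogenization, GABA-B removal with charge-matched GABA-A
    substitution), and a complete oscillation-analysis pipeline: local field
    potential analog, spike density functions, Welch periodograms,
    spectrograms, zero-phase band filtering, trough-referenced spike phases
    with Rayleigh statistics, firing rates, and theta-gamma cross-frequency
    coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
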
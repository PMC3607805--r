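Package: eigamma
Title: Balanced Excitatory-Inhibitory Spiking Networks and Gamma-Band Firing Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of balanced networks of type-I
    conductance-based neurons that generate gamma-band (30-90 Hz) collective
    oscillations while individual cells fire sparsely and irregularly.
    Provides a Hodgkin-Huxley-type single-cell model (f-I curves, rheobase,
    phase response curves), a 2000-neuron random network simulator with
    double-exponential AMPA/GABA conductances, gamma-distributed axonal
    delays and an Ornstein-Uhlenbeck-modulated external Poisson drive, a
    local-field-potential proxy built from synaptic currents, multitaper
    spectral estimation with Slepian tapers, and analyses of the emergent
    bimodal firing-rate distribution including slow/fast spike
    classification, spike-triggered averages, and spike-LFP phase-locking
    histograms. Synthetic fixture generators with known ground truth support
    testing of every analysis stage without running the full network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
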
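Package: coopna
Title: Cooperative Sodium Channel Gating in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cooperative (coupled) gating of clustered
    voltage-gated sodium channels and its consequences for action potential
    initiation and neuronal population coding.  Implements the mean-field
    kinetics of a coupled channel population with its collective activation
    curve and saddle-node (all-or-none) bifurcation analysis; a
    single-compartment Wang-Buzsaki neuron carrying a fraction of cooperative
    sodium channels with open-state-dependent inactivation; phase-plane
    analytics of simulated action potentials (onset rapidness, threshold and
    its variability, monophasic/biphasic classification); and measurement of
    the population firing-rate frequency response under Ornstein-Uhlenbeck
    background noise.  A command-line interface exposes the simulation and
    analysis pipelines with reproducible, config-driven runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
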
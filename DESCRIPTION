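Package: netfluct
Title: Delay-Coupled Oscillator Modeling of Fluctuations in Brain Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates resting-state cortical activity with a delay-coupled
    Kuramoto phase-oscillator network on a structural connectome, converts
    oscillatory activity to BOLD signal through the Balloon/Windkessel
    hemodynamic model, estimates time-resolved functional connectivity with
    tapered sliding windows, characterizes its global topology via signed
    modularity and network cartography (participation coefficient,
    within-module degree z-score), classifies windows into segregated and
    integrated network states or modularity terciles, and compares modeled
    against reference data through a two-stage parameter search and
    degree/strength-preserving surrogate connectomes. Includes synthetic
    generators for modular connectomes and state-switching BOLD so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    deSolve
Config/testthat/edition: 3
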
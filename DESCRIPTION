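Package: plastwm
Title: Plastic-Attractor Model of Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Firing-rate simulation of a two-population working-memory
    network in which fixed feature-selective units and freely-conjunctive
    units are coupled by rapidly plastic Hebbian synapses. The focus of
    attention is an attractor held by mutual excitation between a winning
    conjunctive unit and the attended item's features; unattended items are
    retained activity-silently in normalized synaptic weights and recalled
    by pattern completion from a single probed feature. Includes trial and
    task-set protocols, a battery of simulated behavioral experiments
    (set size, serial position, encoding duration, delay decay, retro-cue,
    excitatory pulse, trial history), neural-decoding analyses (linear
    decoding time courses, attended/unattended cross-decoding, trial-lag
    pattern similarity), three ablation variants, a parameter-calibration
    search, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nnet,
    readr
Config/testthat/edition: 3
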
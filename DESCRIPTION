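Package: dendseq
Title: Two-Compartment Neuron and Recurrent Network Simulator for
    Dendritic Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based simulator of two-compartment pyramidal neurons whose
    somatic and distal dendritic compartments learn by a combined rule:
    BCM-style Hebbian plasticity with a sliding threshold within each
    compartment, plus a coincidence-driven term that approximates canonical
    correlation analysis (CCA) across compartments.  Includes plastic
    dendritic inhibition, short-term synaptic depression and facilitation,
    and a recurrent CA3-like network driven by entorhinal inputs, with
    generators for the behavioral protocols (1D track, Y-maze, branching
    track), place/grid/distractor input models, and analysis tools
    (spatial information per spike, weight-contrast statistics, replay
    sequence counting, reference PCA/CCA).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
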
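Package: pausecode
Title: Rate and Time Coding of Synchronized Purkinje-Neuron Pauses in Cerebellar Nucleus Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how cerebellar nucleus (CN) neurons encode
    synchronized pauses in Purkinje-neuron (PN) simple-spike trains.  Provides a
    gamma-renewal synthesizer for PN spike trains with CV2-based segmentation of
    inter-spike intervals into regular patterns and pauses, transforms that impose
    pause synchrony across a population (pause-beginning, pause-ending, overlapping
    or mixed alignment, with optional spike jitter and forced pre-pause firing
    rates), a two-compartment conductance-based CN neuron model driven by 200
    frequency-dependently depressing inhibitory synapses and 100 mossy-fiber
    AMPA/NMDA synapses with rebound conductances (HCN, low-voltage-activated Ca,
    persistent Na), and the analysis layer: windowed firing-rate increases against
    matched controls, first-spike latency variability with a Lilliefors normality
    gate, peristimulus time histograms, circular vector strength with a
    finite-sample corrected Rayleigh test, and bootstrap/t-test comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
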
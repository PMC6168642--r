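Package: synvesim
Title: Energy-Constrained Synaptic Vesicle Cycle and Dendritic Integration Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates chemical synaptic transmission as a calcium-gated,
    site-limited synaptic vesicle cycle (readily releasable pool preparation,
    exocytosis at a fixed number of release sites, return to the recycling
    pool) together with a metabolic feedback loop in which the ATP budget of
    the synapse regulates the speed of vesicle preparation and thereby the
    release probability. Also provides a Hodgkin-Huxley multi-compartment
    CA1 pyramidal neuron built from a literature-derived morphology table,
    excitatory Poisson synaptic drive per compartment class, and
    information-rate / ATP-per-bit metrics for the resulting spike trains.
    Includes stimulus generators (periodic, Poisson, Gaussian-frequency
    episodes), reproducible experiment runners and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
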
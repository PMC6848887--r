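Package: stngpe
Title: Biophysical Simulation of the Subthalamo-Pallidal Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multicompartment conductance-based simulation of the reciprocally
    connected subthalamic nucleus (STN) - external globus pallidus (GPe) network,
    with short-term-plastic (Tsodyks-Markram) synapses, a metabotropic GABA-B
    cascade, surrogate cortical and striatal spike sources, a parkinsonian
    parameter state, and the spectral, phase-locking and burst analyses used to
    characterize beta-band oscillations in the network. Includes reduced
    parametric neuron morphologies with optional SWC import, a fixed-step
    backward-Euler cable integrator, and reproducible parameter-sweep
    experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    withr
Config/testthat/edition: 3
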
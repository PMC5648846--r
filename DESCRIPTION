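Package: fascicle
Title: Simulation of Axon Growth, Fasciculation and Connectome Formation in the
    Tadpole Spinal Cord
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of developing spinal-cord axons growing
    simultaneously under chemotactic gradient guidance, with attraction
    (fasciculation) or repulsion between axons of the same type, growth
    barriers, commissural midline crossing, probabilistic synaptogenesis onto
    dendrites, connectome metrics, derivative-free calibration of growth
    parameters by compass pattern search, and a simplified conductance-based
    spiking layer with swimming and mid-cycle-spike detectors. All simulation
    state is exchanged as tidy tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
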
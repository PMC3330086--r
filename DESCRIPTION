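Package: dendsyn
Title: Propagation of Synchrony in Spiking Networks with Nonlinear Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of sparse random networks of leaky
    integrate-and-fire neurons whose synchronous excitatory inputs are
    combined through a supra-additive dendritic modulation function, together
    with the Markov-chain theory that predicts when externally initiated
    synchronous spiking propagates persistently and when it dies out.
    Provides exact phase-representation dynamics with delayed delta synapses,
    chain extraction and background-pulse statistics, diffusion-approximation
    and semi-analytic membrane-potential densities, binomial group-size
    transition models with expectation curves and fixed-point analysis, and
    parameter-scan tools for mapping the stable-propagation regime.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
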
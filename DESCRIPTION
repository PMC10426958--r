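Package: jrnet
Title: Jansen-Rit Brain Network Models of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain network modelling with Jansen-Rit neural masses coupled
    through structural connectomes with conduction delays and heterogeneous noisy
    drive. Provides connectome input/output, validation, graph characterisation and
    driver-region variants (parceled, single-node, removed); a synthetic-connectome
    and pseudo-empirical target generator; a stochastic Heun simulator with delay
    buffers and fixed-point/bifurcation utilities; alpha-band phase-locking-value
    functional connectivity, sliding-window dynamical FC and Kolmogorov-Smirnov
    model-fit metrics; coupling and drive parameter-sweep experiments with
    working-point selection; and group-level repeated-measures statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    igraph,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
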
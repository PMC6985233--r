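Package: cyclewarn
Title: Early-Warning Signals for Collapse of Networked Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the last surviving directed cycle in a networked
    dynamical system governed by linear catalytic dynamics, using only the
    node states: when exactly one simple directed cycle remains, the
    normalized attractor quantizes, every component being an integer
    multiple of its minimal non-zero component, with the integer equal to
    the number of directed paths from the cycle to the node.  The package
    implements the quantization detector and its early-warning signal,
    exact structural oracles (simple-cycle enumeration, cycle-to-node path
    multiplicity), the co-evolutionary Jain-Krishna ecosystem model with
    collapse statistics and the analytic expected time-to-collapse e/m,
    event-driven SIS epidemic simulation on directed networks with its
    individual-based mean-field ODE, generalizations to Katz centrality,
    moderately weighted links and the Leslie population-aging model
    (logarithmic quantization), and classical time-series precursor
    baselines (volatility and lagged cross-correlation spectral radii).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
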
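Package: adaptmotif
Title: Stochastic Adaptation and Fold-Change Detection in the Two-State
    Protein Motif
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact and approximate stochastic analysis of the minimal
    'two-state protein' adaptation motif: finite state projection (FSP)
    solutions of the chemical master equation with sparse
    matrix-exponential propagation over piecewise-constant input signals,
    Gillespie stochastic simulation of single cells and cell populations,
    chemical Langevin (Euler-Maruyama) and deterministic closed-form
    counterparts, fold-change-detection statistics on per-interval peak
    responses, and sensitivity/precision adaptation metrics that contrast
    snapshot (population) with time-series (single-cell) sampling to
    diagnose rupture of biological ergodicity. Includes the
    kinase/phosphatase-mediated extension of the motif.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
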
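Package: qmtr
Title: Unconstrained Quantitative Magnetization Transfer Imaging
Version: 0.1.0
Authors@R:
    person("Sam", "Keller", email = "sam.keller@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for unconstrained two-pool
    quantitative magnetization transfer (qMT) imaging. Implements
    Bloch-McConnell spin dynamics with a super-Lorentzian semi-solid pool
    (generalized Bloch model with per-pulse linearized semi-solid relaxation),
    hybrid-state inversion-recovery pulse-train simulation, Cramer-Rao bound
    (CRB) evaluation and CRB-driven pulse-train optimization, dictionary/SVD
    subspace compression, voxel-wise nonlinear least-squares parameter
    mapping, digital-phantom Monte-Carlo experiments, and the exact and
    Taylor-expanded mapping between unconstrained and apparent (constrained)
    MT parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
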
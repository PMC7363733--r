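Package: burstwkb
Title: WKB Mixture Approximations for Bursty Gene Expression with
    Delayed Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Steady-state analysis of a stochastic gene expression model in
    which an inactive protein is produced in bursts, matures through a single
    memoryless activation step, and feeds back on its own burst frequency
    through the active form. In the slow-activation (large-delay) regime the
    stationary joint distribution is approximated by a WKB (large-deviation)
    expansion: the package assembles the tridiagonal matrix whose principal
    eigenvalue defines the Hamiltonian, traces the nontrivial zero-level
    branch giving the derivative of the quasipotential, computes the
    sub-exponential prefactor from the next-order solvability condition, and
    builds Gaussian/Poisson singleton or mixture approximations with WKB
    mode weights. Reference solutions are provided by a sparse truncated
    chemical-master-equation nullvector solver and an exact Gillespie
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
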
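Package: qswkb
Title: WKB Approximation of Quasistationary Distributions and Extinction Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for density-dependent Markov population processes that are
    eventually absorbed at the origin: asymptotic Kolmogorov reversibility
    criteria, analytic WKB approximation of the quasistationary distribution
    (action potential, transport-equation correction, Gaussian curvature
    matrix), Eyring-Kramers-type approximations of the expected time from
    quasistationarity to extinction for multitype birth-death processes, an
    exact truncated-chain oracle, and Gillespie simulation with a censored
    exponential estimation protocol. Includes model factories for
    heterogeneous SIS epidemics, linear-birth quadratic-death processes,
    factorised multitype birth-death families, competition processes, and a
    two-group birth-death process with movement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
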
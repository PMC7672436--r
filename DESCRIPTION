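Package: pairscape
Title: Base-Pair Opening Free-Energy Landscapes for DNA Mismatch Recognition
Version: 0.1.0
Authors@R:
    person("pairscape", "developers", email = "pairscape@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the propensity of DNA base pairs to open
    into the minor groove. Fits base reference frames (including
    syn-transformed frames for non-anti glycosidic orientations), computes
    simple base-pair and step parameters, evaluates base-pair and bending
    collective variables, accumulates adaptive-biasing-force style mean-force
    grids with multiple-walker merging, integrates mean forces into
    free-energy surfaces by Gaussian-process regression with propagated
    uncertainties, reduces 2D surfaces to 1D opening profiles by Boltzmann
    averaging, detects and characterizes thermodynamic states, and computes
    the canonical-versus-mismatch discrimination gap. A seeded overdamped
    Langevin sampler on analytic model surfaces and an idealized B-DNA duplex
    builder provide fully synthetic test beds in place of molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
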
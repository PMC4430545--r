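Package: adaptivepull
Title: Adaptive Steered Langevin Dynamics with Jarzynski Free-Energy
    Estimation and Hydrogen-Bond Pathway Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Staged nonequilibrium pulling simulations on analytic toy
    potentials and bead-spring chains: steered Langevin dynamics (BAOAB)
    with external-work accounting, potential-of-mean-force estimation via
    the Jarzynski exponential work average, naive adaptive steered
    molecular dynamics (stage-wise ensemble contraction by the
    Jarzynski-equality criterion), and full-relaxation adaptive steering
    (zero-work constrained relaxation between stages).  Includes exact
    quadrature oracles for the free energy of low-dimensional systems,
    synthetic polyalanine-like backbone fixtures, geometric hydrogen-bond
    detection (distance/angle criterion) with helical contact
    classification, and work-weighted hydrogen-bond profiles along the
    pulling pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
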
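Package: slugsim
Title: Viscoelastic Cell-Based Simulation of Cell Sorting in the
    Dictyostelium Slug
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Off-lattice, force-based simulation of the Dictyostelium
    discoideum slug in three dimensions.  Each cell is a volume-conserving
    ellipsoid whose axes behave as standard linear solids; cells interact
    through adhesion, overlap (rheological) repulsion, nucleus repulsion
    and confining boundary forces, and move by overdamped force balance
    with a contact-area weighted cell-cell drag matrix.  Differential
    motive force and differential chemotactic directionality between the
    prestalk and prespore cell types drive cell sorting, quantified by the
    relative anterior-posterior position of the prestalk cells over
    ensembles of stochastic realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
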
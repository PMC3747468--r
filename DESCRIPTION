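Package: screwopt
Title: Multiobjective Design Optimization of Spinal Pedicle Screws
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Surrogate-assisted multiobjective optimization of spinal pedicle
    screw geometry. Trains small feed-forward backpropagation neural networks
    as surrogates for finite-element bending stress and pullout force over a
    six-variable screw parameterization, sweeps a weighted-sum fitness with a
    binary-encoded genetic algorithm, and extracts the Pareto front and its
    knee-region optimal designs. Includes the L25 orthogonal-array training
    data, reference commercial screw geometries, and a closed-form pseudo
    finite-element generator for end-to-end testing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    quadprog
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
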
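Package: plasmidmc
Title: Monte Carlo Simulation of Plasmid DNA Supercoiling with a Local
    Three-Vertex Move
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Metropolis Monte Carlo simulator for closed
    circular (plasmid) DNA. The molecule is reduced to a closed
    equal-segment skeleton (~30 bp per segment) deformed by a local
    three-vertex move that preserves segment lengths and connectivity,
    with standard, biased (adaptive-angle) crankshaft and reptation moves
    as baselines. Elastic energy combines a quadratic bending term and a
    torsional term driven by the linking-number deficit and the writhe,
    computed by the auxiliary-chain (Lk - Tw) method with a Gauss-integral
    cross-check. Knotted trial conformations are rejected by an
    Alexander-polynomial test before the energy evaluation. Includes
    constant-temperature and simulated-annealing drivers, per-slice
    acceptance/displacement metrics, XYZ/CSV input-output, knot fixtures
    (trefoil, figure-eight) and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
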
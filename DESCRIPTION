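Package: atriasim
Title: Stochastic Subcellular Calcium Dynamics in Atrial Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates calcium-induced calcium release in a two-dimensional
    atrial myocyte at submicron resolution. The cell is represented by two
    co-located homogenized concentration fields (cytosol and sarcoplasmic
    reticulum) with spatially varying volume fractions and effective
    diffusion coefficients, z-line microstructure, stochastic Markov gating
    of ryanodine-receptor clusters and L-type calcium channels, and the
    standard membrane and uptake fluxes (GHK L-type current, sodium-calcium
    exchange, SERCA, immobile buffers). Includes geometry builders for
    calcium-release-unit placement, paced-transient, wave-propagation and
    resting-spark protocols, and analysis tools for sparks, wave fronts and
    cluster spatial statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
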
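Package: ldacv
Title: Position-Based Linear Discriminant Analysis Reaction Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds one-dimensional reaction coordinates for conformational
    transitions by applying linear discriminant analysis (LDA) directly to
    particle positions. Configurations are aligned into size-and-shape space
    with Mahalanobis-optimal rigid-body transformations under a Kronecker
    (particle-by-particle) covariance model; a discriminant direction is
    trained between two labelled states through an SVD formulation that
    remains valid for singular scatter matrices; the coordinate can be
    evaluated and biased on the fly with well-tempered metadynamics or
    OPES in a bundled Langevin toy-dynamics engine; and candidate
    coordinates are validated with committor and free-energy-surface
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
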
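Package: cjsched
Title: Scalable Scheduling Distributions for Bradley-Terry Comparative
    Judgement Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs static experimental designs (scheduling
    distributions over object pairs) for comparative judgement studies
    analysed with the Bradley-Terry model. Provides the standard
    principal-component design, which spectrally decomposes the
    pairs-of-pairs covariance matrix of prior quality differences, and a
    scalable reduced basis decomposition (RBD) route that produces the
    same design without ever forming that matrix. Includes prior
    covariance constructors (graph-Laplacian, Toeplitz, inverse-Wishart,
    matrix-exponential adjacency), Kullback-Leibler design diagnostics,
    eigenvalue interlacing and rank-structure checks, Bayesian MAP
    fitting of the Bradley-Terry model with a Laplace posterior
    covariance, comparison simulation, and a seeded benchmark harness
    for two-phase (sequential) study workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
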
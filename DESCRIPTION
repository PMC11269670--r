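Package: evoburden
Title: Evolutionary Failure Simulation and Gene-Expression Burden
    Quantification for Engineered DNA Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolutionary failure of burdensome engineered DNA
    constructs in growing cell populations using a two-type
    engineered/failed-mutant model (deterministic ODE and exact/tau-leaping
    stochastic variants), with culture-scale division and failure-rate
    calculators. Implements a complete microplate burden-quantification
    pipeline: blank subtraction and baseline alignment of plate-reader time
    series, sliding-window nonlinear least-squares fitting of maximum growth
    and fluorescent-protein production rates, Gaussian-kernel-density plate
    normalization, one-tailed burden tests with Benjamini-Hochberg
    correction, anchored Deming regression of growth rate on gene-expression
    capacity, and classification of burden into expression and
    non-expression sources. A seeded synthetic plate generator with known
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
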
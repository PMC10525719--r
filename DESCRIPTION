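Package: invae
Title: Information-Navigated Variational Autoencoder for Single-Cell Perturbation Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unseen single-cell perturbation responses for held-out cell
    types with an information-navigated variational autoencoder (INVAE). The latent
    space is split into a condition-invariant part and a condition-specific
    homogeneous part using differentiable one-way ANOVA navigation losses, a
    beta-TCVAE total-correlation decomposition disentangles latent dimensions, and a
    learned projection layer maps control-state codes into the perturbed-state
    space. Includes preprocessing for annotated expression matrices (CSV, MatrixMarket,
    h5ad), a synthetic data generator with known ground truth, an alternating
    training schedule, R-squared evaluation on all genes and top differentially
    expressed genes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
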
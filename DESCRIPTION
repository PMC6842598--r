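Package: sindyae
Title: Joint Discovery of Latent Coordinates and Sparse Governing Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers parsimonious dynamical models from high-dimensional
    time-series data by jointly training a feedforward autoencoder and a
    sparse regression onto a library of candidate functions (SINDy). Provides
    exact chain-rule propagation of first and second time derivatives through
    the encoder and decoder, sequentially thresholded least squares, Adam
    training with periodic coefficient pruning, generators for three synthetic
    benchmark systems (a Legendre-mode embedding of the chaotic Lorenz system,
    a lambda-omega reaction-diffusion spiral wave, and a rendered nonlinear
    pendulum video), and evaluation utilities including sparsity-pattern
    matching under per-coordinate rescaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
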
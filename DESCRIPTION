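Package: entropics
Title: Entropy Estimators for Time Series and Image Complexity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A command-line friendly toolkit for entropic time series and
    image analysis. Provides eighteen single-series ("base") entropy
    estimators (approximate, sample, fuzzy, permutation, dispersion,
    distribution, spectral, Kolmogorov and related symbolic and geometric
    measures), eight cross-entropy estimators for paired series, four
    bidimensional estimators for real-valued matrices, and classic,
    composite, refined-composite, refined and hierarchical multiscale
    engines that accept any base or cross estimator. Includes generators
    for standard synthetic benchmark signals (Gaussian and uniform
    noise, Lorenz and Henon attractors, linear chirp, random and
    Mandelbrot matrices), plain-text signal input and output, result
    serialisation and diagnostic plots (multiscale curves, second-order
    difference plots, gridded Poincare censuses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
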
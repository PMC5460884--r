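Package: ldmap
Title: Lifetime Density Analysis of Time-Resolved Spectroscopic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lifetime density analysis (LDA) of time-resolved
    difference-absorption data. Approximates transient signals by a
    semi-continuous sum of ~100 instrument-response-convolved exponential
    decays and solves the resulting ill-posed inverse problem per wavelength
    channel by truncated-SVD, Tikhonov, LASSO (orthogonalizing iterative
    algorithm) or elastic-net regularization, assembling the pre-exponential
    amplitudes into lifetime density maps. Includes SVD-based global analysis
    via variable projection, hyperparameter selection by generalized
    cross-validation, Mallows' Cp and the L-curve, and generators for
    synthetic kinetic schemes (heterogeneous decay, dynamic band motion, and
    a combined scenario) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
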
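Package: brainparc
Title: Evolutionary Brain Parcellation Models and Macroconnectome Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic models of brain parcellation by iterative region
    fragmentation, in which the region chosen to split is drawn with
    probability proportional to volume^mu. Provides the fragmentation
    simulator, lognormality diagnostics for region-volume tables (Gaussian
    fits of log volumes, Kolmogorov-Smirnov tests, Q-Q data),
    simulation-based confidence intervals for the bias exponent mu inverted
    from the observed dispersion of log region volumes, the rank-one
    (outer-product) region-to-region connectivity model with fraction of
    labeled neurons (FLN) normalization and log-log power-law exponent
    fits, and the multiplicative Hebbian plasticity rule whose fixed point
    yields the outer-product power-law connectome. Includes synthetic
    fixture generators, CSV/Newick tree input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
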
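Package: threshmap
Title: Gaussian Process Threshold Mapping for Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial estimation of perceptual thresholds on retinal-implant
    electrode grids by Gaussian process regression. Provides RBF, Matern
    (nu = 1.5) and hybrid covariance kernels with log-marginal-likelihood
    hyperparameter optimization; uniform random, Poisson-disk spatial and
    uncertainty-driven adaptive electrode sampling strategies; a synthetic
    threshold-map generator with censoring at the device safety limit; and
    a MAPE-based benchmark comparing kernels and sampling strategies with
    Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
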
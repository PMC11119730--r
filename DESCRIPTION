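Package: infoest
Title: Non-Parametric Estimation of Entropy, KL Divergence, and Mutual
    Information from Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three families of non-parametric estimators for differential
    entropy, Kullback-Leibler divergence, and mutual information on
    multi-dimensional continuous samples: kernel density estimation with a
    multivariate Gaussian kernel and Silverman bandwidth (resubstitution and
    integral plug-in forms), histogram estimators with Sturges/Scott/
    Freedman-Diaconis bin-width rules plus the one-dimensional Quantile
    Spacing entropy estimator, and distance-based k-nearest-neighbor
    estimators (Kozachenko-Leonenko entropy, Wang et al. KL divergence,
    Kraskov et al. mutual information) backed by an exact kd-tree. Includes
    a registry of eight synthetic benchmark distributions with analytical or
    adaptive-quadrature reference values and a seeded sweep harness that
    evaluates estimator accuracy as a function of sample size and
    hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
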
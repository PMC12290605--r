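Package: tvfc
Title: Time-Varying Functional Connectivity Estimation with Wishart
    Processes and Classical Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of time-varying functional connectivity (TVFC)
    between multivariate BOLD-like time series. Implements a Wishart
    process estimator built from sparse variational Gaussian processes
    fitted by stochastic maximization of a Monte-Carlo evidence lower
    bound, together with static covariance, sliding-window (with
    cross-validated window length) and DCC(1,1)-GARCH(1,1) baselines.
    Includes synthetic covariance simulators with fMRI-like
    autocorrelated noise, RMSE recovery and leave-every-other-out
    imputation benchmarks, TVFC summary measures, and downstream
    statistics (morphometricity via REML variance components, edgewise
    ICC, I2C2, k-means brain states, and GLM stimulus prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, pracma, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
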
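Package: noisebm
Title: Sampling Networks with Private, Shared and Network-Generated Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation and calibration of Boltzmann-machine-like
    sampling networks whose stochasticity is supplied either intrinsically, by
    private additive Gaussian noise, by a finite shared pool of independent
    stochastic binary units, or by a deterministic recurrent
    inhibition-dominated network. Provides exact Boltzmann target
    distributions for small networks, activation-function calibration between
    logistic and error-function units, mean-field theory for rates and
    population-averaged covariances of the noise network including the
    shared-input correlation decomposition, Kullback-Leibler evaluation of
    sampled state distributions, contrastive-divergence training of fully
    visible Boltzmann machines with class rebalancing, and config-driven
    figure-style parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    tidyr
Config/testthat/edition: 3
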
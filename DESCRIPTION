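Package: bayspar
Title: Bayesian Spatially-Varying Calibration of the TEX86 Paleothermometer
Version: 1.0.0
Authors@R: person("BAYSPAR", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian spatially-varying regression calibration of
    the TEX86 archaeal-lipid proxy against surface and gamma-weighted
    subsurface ocean temperatures, with Gibbs/Metropolis MCMC fitting on
    20-by-20 degree grid boxes under a Matern(3/2) Gaussian-process prior,
    Bayesian inversion of downcore TEX86 series into probabilistic
    temperature reconstructions, ensemble analytics (warmest-interval
    probabilities, epoch differences), core-top database parsing and
    validation, gamma-weighted subsurface calibration targets, and a
    synthetic-data generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
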
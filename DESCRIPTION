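Package: riceAssim
Title: Crop-Model/Remote-Sensing Data Assimilation for Rice by
    Metropolis-Hastings MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recalibrates rice crop-management parameters (sowing date,
    seeding rate, nitrogen amount) by assimilating NDVI-derived estimates
    of leaf area index (LAI) and plant nitrogen accumulation (PNA) into a
    deterministic daily-timestep rice growth model with a random-walk
    Metropolis-Hastings sampler, then predicts yield with posterior
    uncertainty quantified as root-mean-square dispersion (RMSD) of
    posterior-predictive ensembles.  Ships a pluggable surrogate crop
    model, NDVI spectral calibration with saturation diagnostics, a
    seeded synthetic-experiment generator emulating multi-rate nitrogen
    trials, and evaluation metrics (RE, RMSE, RMSD, R squared) comparing
    assimilation against direct spectral inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
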
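Package: memperm
Title: Membrane Permeability from Permeant Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates membrane permeability of small molecules (oxygen,
    water) from time-resolved permeant trajectories. Implements the
    crossing-counting estimator with the 0.5-crossing correction for
    permeants initially inside the bilayer, the inhomogeneous
    solubility-diffusion integral, Bayesian inference of free-energy and
    anisotropic position-dependent diffusion profiles from binned transition
    counts via a discretized Smoluchowski rate matrix with Bessel-mode radial
    likelihood and infinite-lag extrapolation, thickness-dependent partition
    coefficients, three-nearest-neighbor permeation-pathway classification,
    and spin-label oximetry power-saturation analysis. Includes an overdamped
    Brownian-dynamics generator with known free-energy and diffusion
    profiles, and a toy microdomain membrane, for validation with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
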
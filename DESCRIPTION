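Package: goldrim
Title: Quantification of Nanogold Particle Density Along Membrane Pore
    Rims in Cryo-EM Projection Images
Version: 1.0.0
Authors@R:
    person("Goldrim", "Developers", email = "goldrim@example.org",
           role = c("aut", "cre"))
Description: Detects nanogold-labeled protein particles in calibrated
    cryo-electron microscopy projection images by intensity-band and
    physical-area thresholds, and quantifies their spatial organization
    around membrane pores: region-of-interest particle densities,
    particle-to-pore-edge distances, pore perimeter estimation from
    inner/outer rim boundaries, particle-area-versus-circumference
    regression, interparticle spacing, projection foreshortening error
    bounds, and exact Mann-Whitney rank comparisons.  Includes a
    synthetic-scene generator that renders porated spherical vesicles
    decorated with rim-bound gold particles at a fixed linear density,
    with exact ground truth, plus a reproducible simulate/measure/report
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
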
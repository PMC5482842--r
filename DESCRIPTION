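Package: nitroscape
Title: Community-Scale Foliar d15N Isoscapes from Terrain and Invader Proximity
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to model small-scale spatial variation of foliar nitrogen
    isotope ratios (d15N) in invaded dune vegetation. Derives terrain
    predictors (slope, multiple-flow-direction wetness index, topographic
    position landforms) and invader-proximity predictors (distance, area and
    relative elevation of the nearest N2-fixing canopy) from gridded
    elevation and cover data, fits additive mixed models with penalized
    spline smooths and nested random intercepts, ranks all term subsets by
    AICc with Akaike weights, validates by repeated random train/test splits
    and spatial residual diagnostics (Moran's I, semivariogram), and predicts
    continuous d15N isoscape rasters with scenario decompositions. Includes a
    synthetic landscape generator emulating the sampling design and effect
    magnitudes of field studies of acacia invasion in coastal dunes, so the
    full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
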
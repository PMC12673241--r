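Package: refugiaTrack
Title: Microclimatic Niches, Refugia Statistics and Post-Breeding Movement
    for Partially Migratory Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the realized microclimatic niche of tracked
    animals and relate breeding-season microclimate to post-breeding
    movement. From GPS relocations and hourly micro-scale temperature
    grids the package computes 500 m buffer temperature statistics and
    microclimate refugia metrics, builds an environmental-space niche by
    principal component analysis with bivariate kernel density contours,
    measures seasonal niche overlap and centroid dissimilarity, derives
    migration distances from daily utilization distributions, and fits
    linear mixed-effects models linking refugia availability to distance
    travelled and distance to seasonal niche dissimilarity. A synthetic
    world generator with known effect sizes supports end-to-end testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    KernSmooth,
    lme4,
    lmerTest,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
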
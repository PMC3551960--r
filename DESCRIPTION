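Package: seashift
Title: Multi-Model Projection of Climate-Driven Marine Range Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing climate-driven distribution shifts of marine
    species on a regular latitude-longitude grid with an ensemble of three
    species distribution models: a trapezoidal bioclimatic envelope model, a
    minimal presence-only maximum-entropy model, and a simplified dynamic
    bioclimate envelope model with logistic growth and neighbour dispersal.
    Includes synthetic scenario and virtual-species generators, occurrence
    quality control and gridding, suitability thresholding (fixed and
    ROC-selected), dispersal scenarios, depth and region clipping, latitudinal
    centroid shifts, range-area change, Schoener's D niche overlap, and
    protected-area habitat-suitability change, orchestrated by a config-driven
    pipeline over species x model x climate-scenario x threshold combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
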
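Package: gardenclim
Title: Common-Garden Trait Genetics and Climate Projection for Forest Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for half-sib common-garden (provenance) trials
    of forest trees: leaf spectral indices (photochemical reflectance index
    and modified red-edge NDVI), specific leaf area and wood density from
    field measurements, REML variance components and narrow-sense
    heritability under a mixed mating system, population differentiation
    with Tukey all-pairs comparisons and compact letter displays,
    family-mean principal components and trait-pair regressions,
    bounded-smoothness generalized additive models of traits on
    climate-of-origin with exhaustive subset selection, projection of trait
    surfaces over current and future climate rasters with extrapolation
    masking, proportional-change maps, and tests for decoupling of trait
    correlations between climate scenarios. Includes a synthetic plantation
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    mgcv,
    multcomp,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
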
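Package: endemap
Title: Quantitative Delimitation of Areas of Endemism from Point Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing biogeographic regionalization hypotheses from
    point occurrence records. Implements kernel-based Geographical
    Interpolation of Endemism (GIE) with range-size categories and consensus
    surfaces, a species-to-area fit index, a species composition break
    pipeline (Bray-Curtis dissimilarity, turnover/nestedness partition,
    non-metric multidimensional scaling, Moran's I, ordinary kriging of
    ordination scores and RGB composites), Monmonier's maximum-difference
    barrier detection on Delaunay/Voronoi networks, desk-scale Parsimony
    Analysis of Endemicity with constrained searches, sampling-effort
    surfaces with spatial-autocorrelation-corrected correlation tests,
    maximum-likelihood classification of composition rasters, and a
    synthetic-data generator with planted areas of endemism and river
    barriers for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    deldir,
    geosphere,
    jsonlite,
    MASS,
    phangorn,
    sp,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
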
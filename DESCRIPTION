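Package: rarebef
Title: Rare and Abundant Soil Taxa, Ecosystem Multifunctionality, and
    Assembly Stochasticity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the diversity of rare versus abundant soil
    phylotypes (archaea, bacteria, fungi, protists) relates to ecosystem
    multifunctionality along environmental gradients.  Provides abundance
    partitioning of OTU tables, min-max standardized richness and
    multidiversity, three multifunctionality indices (averaging,
    service-weighted, principal-coordinate), supporting-phylotype screens,
    co-occurrence network construction with FDR-thresholded Spearman
    correlations, an abundance-weighted Bray-Curtis null-model
    stochasticity ratio, moving-window biodiversity-ecosystem-function
    slope estimation, and a seeded synthetic-data generator that emulates
    a 228-field multitrophic survey so the full pipeline can be exercised
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse
Config/testthat/edition: 3
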
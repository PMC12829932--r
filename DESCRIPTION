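Package: lucisr
Title: Hierarchical Land-Suitability Modeling and Human-Wildlife Conflict Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open implementation of the Land Use Conflict Identification
    Strategy (LUCIS) for human-wildlife conflict assessment. Builds per-goal
    land-suitability surfaces for agriculture, human settlement and wildlife
    by weighted linear combination through a three-tier goal/objective/
    sub-objective hierarchy; derives criterion weights with the Analytic
    Hierarchy Process (principal eigenvector, consistency ratio); rescales
    composites to the 1-9 suitability scale; bins suitability into 1-3
    preference classes with exact Jenks natural-breaks classification;
    overlays preferences into a four-class conflict map; and quantifies each
    factor group's influence with one-at-a-time map-removal sensitivity
    analysis. Includes a seeded synthetic-landscape generator (autocorrelated
    random fields, road-clustered settlements and farms, protected areas) so
    the full pipeline is reproducible without proprietary data, plus minimal
    planar raster/vector primitives (rasterization, Euclidean distance
    surfaces, slope, grid alignment, multi-resolution decision units, zonal
    statistics) operating in projected metric coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
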
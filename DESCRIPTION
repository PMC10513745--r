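Package: threatscape
Title: Threat-Degree Mapping of Human Expansion Impacts on Biodiversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the threat that cropland and artificial-surface
    expansion between two land-cover epochs poses to threatened species.
    Provides terrain stratification into lowlands and highlands from a
    digital elevation model, detection of 8-connected human-expansion
    patches, overlay counting of threatened (CR/EN/VU) species ranges,
    a composite threat-degree index (the geometric mean of min-max
    normalized density surfaces of patch number, patch area, and species
    involvement on a 1 km grid), mean/standard-deviation threat-level
    classification, zonal and protected-area summaries, and a seeded
    synthetic-landscape generator with exact ground truth for end-to-end
    validation. All analysis happens in a planar equal-area frame; rasters
    are read and written as single-band GeoTIFF and vectors as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
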
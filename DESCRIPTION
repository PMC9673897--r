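Package: sdindex
Title: Ease of Social Distancing Index for Urban Areas
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates urban extents from a settlement-model raster and
    quality-flagged urban centres, constructs street-block spatial units from
    linear and land-use boundary features, and scores each unit for ease of
    social distancing by combining a building-footprint coverage score with a
    population-density score derived from a hexagonal-packing spacing model.
    Includes a seedable synthetic-city generator with planted ground truth, a
    technical-validation module comparing score distributions across settlement
    types, plain-text geospatial input/output (GeoJSON vectors, ESRI ASCII
    grid rasters), and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    geosphere,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    sp,
    spatstat.geom,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
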
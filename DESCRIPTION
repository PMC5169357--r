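Package: roadscape
Title: Screening Potential Food-Production Benefits and Environmental Costs
    of Road Development on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proactive, spatially explicit screening of road
    building and road improvement plans. Builds an aggregate potential
    food-production benefit surface (crop yield gaps weighted by harvested
    area and energy content, multiplied by travel-time isolation) and an
    aggregate environmental-cost surface (terrestrial-vertebrate range
    importance, carbon-stock loss on conversion, and local climate
    regulation), each on an equal-area decile 0-1 scale, and intersects them
    into a bivariate planning classification. Includes sensitivity analyses
    (alternative yield-gap data, maximum instead of mean cost aggregation,
    population-based benefits), existing-road density surfaces, per-proposal
    buffer zonal statistics and along-route profiles, and a seeded synthetic
    landscape generator so the whole pipeline is testable without external
    GIS data. Rasters are exchanged as plain-text ESRI ASCII grids and
    vectors as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
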
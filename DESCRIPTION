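Package: hydroniche
Title: Hydrological Habitat Occupancy Analysis for Plant Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species-level hydrological habitat position and range
    from georeferenced occurrence records and co-registered bioclimatic
    rasters (mean annual precipitation, dry-month precipitation,
    precipitation seasonality, aridity index, and the ratio of actual to
    potential evapotranspiration). Provides deterministic occurrence-record
    cleaning, per-point raster extraction, PCA climate spaces on species
    means and ranges, group-normalized pairwise interval-overlap statistics,
    geodesic extent-of-occurrence areas on the WGS84 ellipsoid, and the
    associated hypothesis-test batteries relating habitat position, habitat
    range, geographic range size and genus-level diversity. A seeded
    synthetic landscape and occurrence generator with known truth supports
    testing of every stage without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
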
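#!/usr/bin/env Rscript
# Stage 6: geographic range sizes.
#
# Fits the convex hull of each species' presence points in lon/lat and
# measures its geodesic area on the WGS84 ellipsoid (extent of occurrence,
# km^2).

suppressPackageStartupMessages(library(hydroniche))

out <- "results/analysis"
records <- read.csv(file.path(out, "cleaned_occurrences.csv"))

geo <- species_georanges(records)
write.csv(geo, file.path(out, "georanges.csv"), row.names = FALSE)
message(sprintf("range sizes for %d species: %.0f-%.0f km^2 (%d degenerate)",
                nrow(geo), min(geo$area_km2), max(geo$area_km2),
                sum(geo$degenerate)))
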
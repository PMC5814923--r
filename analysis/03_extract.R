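#!/usr/bin/env Rscript
# Stage 3: bioclimatic extraction and species summaries.
#
# Samples the six raster layers at every retained presence point (AET/PET
# as a per-point ratio), reduces to per-species habitat position (mean) and
# habitat range (max - min) for the five indicators, and screens variable
# collinearity across species means.

suppressPackageStartupMessages(library(hydroniche))

out <- "results/analysis"
stack <- read_climate_stack("results/data/stack")
records <- read.csv(file.path(out, "cleaned_occurrences.csv"))

values <- extract_values(stack, records)
log <- attr(values, "drop_log")
message(sprintf("extracted %d points (%d outside grid, %d on nodata)",
                nrow(values), log$n_outside, log$n_nodata))

summaries <- summarize_species(values)
message(sprintf("summaries for %d species", nrow(summaries)))

screen <- variable_collinearity_screen(summaries)
flagged <- screen$flagged
message(sprintf("collinearity screen: %d pair(s) above r2 = 0.70%s",
                nrow(flagged),
                if (nrow(flagged) > 0) {
                  paste0(" (", paste(flagged$var1, flagged$var2, sep = "~",
                                     collapse = ", "), ")")
                } else ""))

write.csv(values, file.path(out, "point_values.csv"), row.names = FALSE)
write.csv(summaries, file.path(out, "species_summaries.csv"), row.names = FALSE)
write.csv(screen$r2, file.path(out, "collinearity_r2.csv"))
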
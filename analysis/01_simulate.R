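#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Generates the gradient-dominated climate landscape and the 50-species
# niche cohort (bivariate Gaussian niches on MAP and P_seas, breadth scale
# factors spanning 0.05-0.5 of each variable's landscape range), injects
# the three classes of contaminant record that quality control must remove,
# and writes every downstream input: the raster stack (ESRI ASCII grids),
# the contaminated occurrence CSV with truth labels, native-region boxes,
# the institution blocklist, and genus / functional-type / richness tables.

suppressPackageStartupMessages(library(hydroniche))

seed <- 7L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_study_cohort(seed = seed)
message(sprintf("landscape: %d x %d cells; cohort: %d species x %d points",
                cohort$stack$n_rows, cohort$stack$n_cols,
                nrow(cohort$truth), cohort$truth$n_points[1]))

write_climate_stack(cohort$stack, file.path(out, "stack"))
write.csv(cohort$truth, file.path(out, "truth.csv"), row.names = FALSE)

boxes <- native_boxes_from_occurrences(cohort$occurrences)
institutions <- data.frame(name = c("herbarium_A", "garden_B"),
                           longitude = c(-74.2, -73.1),
                           latitude = c(-1.1, -2.3))
cont <- inject_contaminants(cohort$occurrences, boxes,
                            contamination_spec(n_duplicates = 3,
                                               institution_points = institutions[, 2:3],
                                               n_institution = 2,
                                               n_out_of_range = 2,
                                               seed = seed))
message(sprintf("occurrences: %d clean + %d contaminant records",
                sum(cont$label == "clean"), sum(cont$label != "clean")))
write.csv(cont, file.path(out, "occurrences_labelled.csv"), row.names = FALSE)
write.csv(cont[, c("species", "longitude", "latitude", "record_id")],
          file.path(out, "occurrences.csv"), row.names = FALSE)
write.csv(boxes, file.path(out, "native_regions.csv"), row.names = FALSE)
write.csv(institutions, file.path(out, "institutions.csv"), row.names = FALSE)

# genus-like groups of varying size (3-9 species) and functional types
# assigned round-robin (no built-in range-size differences between types);
# genus richness is the assigned size scaled up, emulating partial sampling
set.seed(seed)
sizes <- c(3, 4, 5, 6, 7, 8, 9, 8)
genus <- rep(sprintf("genus%02d", seq_along(sizes)), sizes)
species <- sample(cohort$truth$species)  # random genus membership
groups <- data.frame(species = species, group = genus)
ftypes <- data.frame(species = cohort$truth$species,
                     functional_type = rep(c("C3_mesic", "C3_succulent",
                                             "C3_CAM", "CAM_succulent"),
                                           length.out = 50))
richness <- data.frame(group = sprintf("genus%02d", seq_along(sizes)),
                       richness = sizes * 4)
write.csv(groups, file.path(out, "groups.csv"), row.names = FALSE)
write.csv(ftypes, file.path(out, "functional_types.csv"), row.names = FALSE)
write.csv(richness, file.path(out, "richness.csv"), row.names = FALSE)
message("inputs written to ", out)
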
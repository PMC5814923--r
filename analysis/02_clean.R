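#!/usr/bin/env Rscript
# Stage 2: occurrence-record quality control.
#
# Loads the contaminated occurrence CSV and applies the three filters
# (within-species duplicates, institution coordinates, outside-native-range
# records) plus the minimum-three-points rule, then checks the result
# against the generator's truth labels.

suppressPackageStartupMessages(library(hydroniche))

dat <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loaded <- load_occurrences(file.path(dat, "occurrences.csv"))
message(sprintf("loaded %d records (%d rejected rows)",
                nrow(loaded$records), nrow(loaded$rejected)))

boxes <- read.csv(file.path(dat, "native_regions.csv"))
institutions <- read.csv(file.path(dat, "institutions.csv"))
cleaned <- clean_occurrences(loaded$records, boxes, institutions[, 2:3],
                             institution_tolerance_deg = 0)

labelled <- read.csv(file.path(dat, "occurrences_labelled.csv"))
truth_clean <- sort(labelled$record_id[labelled$label == "clean"])
agree <- identical(sort(cleaned$records$record_id), truth_clean)
message(sprintf("retained %d records across %d species; matches truth labels: %s",
                nrow(cleaned$records), length(unique(cleaned$records$species)),
                agree))
stopifnot(agree)

write.csv(cleaned$records, file.path(out, "cleaned_occurrences.csv"),
          row.names = FALSE)
write.csv(cleaned$report, file.path(out, "cleaning_report.csv"),
          row.names = FALSE)
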
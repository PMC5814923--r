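#!/usr/bin/env Rscript
# Stage 4: multivariate habitat spaces.
#
# Fits the PCA climate space on species means (habitat position) and on
# species ranges (habitat range), reports the variance captured by the
# first two components, and measures each genus's diversity as the convex
# hull of its species scores in PC1-PC2.

suppressPackageStartupMessages(library(hydroniche))

out <- "results/analysis"
summaries <- read.csv(file.path(out, "species_summaries.csv"))
groups <- read.csv("results/data/groups.csv")

for (kind in c("position", "range")) {
  space <- fit_habitat_space(summaries, kind)
  ve <- 100 * space$variance_explained
  message(sprintf("%s space: PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%%)",
                  kind, ve[1], ve[2], ve[1] + ve[2]))
  write.csv(space$loadings, file.path(out, paste0("loadings_", kind, ".csv")))
  write.csv(space$scores, file.path(out, paste0("scores_", kind, ".csv")))
  hulls <- group_hull_area(space, groups)
  write.csv(hulls, file.path(out, paste0("genus_hulls_", kind, ".csv")),
            row.names = FALSE)
  message(sprintf("  genus hulls: %d genera with >= 3 species", nrow(hulls)))
}
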
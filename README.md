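# hydroniche

Estimating species-level **hydrological habitat occupancy** from
georeferenced presence records and bioclimatic rasters, and testing how it
relates to geographic range size and diversity. The package implements the
full analysis pipeline used in macroecological studies of
precipitation-driven niche differentiation (the motivating system is the
terrestrial bromeliads, a Neotropical radiation whose ecological
diversification is strongly hydrological), together with a seeded synthetic
landscape/occurrence generator so every stage is testable without any
external downloads.

## What it computes

For each species with at least three cleaned presence points, and for the
five hydrological indicators — mean annual precipitation (MAP, mm),
aridity index (AI, stored as `round(10^4 * MAP / PET)`), the ratio of
actual to potential evapotranspiration (AET/PET, per point), dry-month
precipitation (P_dry, mm) and precipitation seasonality (P_seas, %):

* **Habitat position** `mean(v)` and **habitat range** `max(v) - min(v)`
  per indicator, from raster values extracted at each presence point.
* **PCA climate spaces** on log10(x+1)-transformed, unit-variance species
  means (position space) and ranges (range space), with deterministic
  component signs, plus per-genus convex-hull areas in PC1–PC2 as
  diversity measures.
* **Within-group interval overlap**: for species *i*, *j* the statistic
  `max(0, min(max_i, max_j) - max(min_i, min_j))`, averaged over distinct
  pairs and normalized by the group's mean species-level range — a
  dimensionless overlap in [0, 1].
* **Geographic range size** as the geodesic area (km², WGS84 ellipsoid) of
  the convex hull of the species' points (extent of occurrence).
* **Hypothesis batteries**: position-vs-range regressions per indicator;
  log10 range-size vs each indicator's range; genus richness vs
  PC-hull diversity; one-way ANOVA of log range size across functional
  types; and a sample-size sensitivity screen.
* **Record cleaning** with a fixed rule order (within-species duplicates →
  institution coordinates → outside-native-range → minimum three points)
  and a count-conserving report.

## Worked example

The bundled study cohort simulates 50 species (100 points each) on a
gradient-dominated synthetic landscape, with bivariate Gaussian niches
whose breadth scale spans a tenfold range — so each species' climatic
tolerance is known truth:

```r
library(hydroniche)
cohort <- simulate_study_cohort(seed = 7)
summ   <- summarize_species(extract_values(cohort$stack, cohort$occurrences))

fit_habitat_space(summ, "position")
#> habitat_space (position): 50 species, 5 components
#> variance explained: 79.8% 19.0% 1.0% 0.1% 0.0%
#>            PC1    PC2    PC3    PC4    PC5
#> MAP      0.494  0.134 -0.389 -0.208  0.737
#> AI       0.490  0.201 -0.080 -0.613 -0.581
#> AET_PET  0.408  0.578  0.580  0.402  0.041
#> P_dry   -0.354  0.713 -0.564  0.162 -0.145
#> P_seas   0.473 -0.313 -0.433  0.627 -0.312
```

Two components carry almost all the variance, with the moisture-linked
indicators (MAP, AI, AET/PET) loading together on PC1 — the two-axis
structure this climate space is designed to expose. Geographic range size
tracks habitat range:

```r
geo <- species_georanges(cohort$occurrences)
m   <- merge(summ, geo, by = "species")
linear_regression(m$P_seas_range, m$area_km2, log_y = TRUE, label = "P_seas")
#>    label  n slope intercept   r2  p_value sign log_x log_y
#> 1 P_seas 50 0.013      4.59 0.67 3.95e-13    + FALSE  TRUE
```

i.e. species tolerating a wider span of precipitation seasonality occupy
much larger areas (r² = 0.67). And the generator's specified niche breadth
is recovered by the estimated habitat range:

```r
tm <- merge(summ, cohort$truth, by = "species")
cor(tm$MAP_breadth, tm$MAP_range, method = "spearman")
#> [1] 0.848
```

The `analysis/` directory holds the full numbered workflow
(`01_simulate.R` … `07_hypotheses.R`): simulation with injected
contaminant records, cleaning validated against truth labels, extraction,
climate spaces, overlap tables, range sizes and the hypothesis batteries,
writing all tables under `results/`. Run them in order from the repository
root with `Rscript analysis/01_simulate.R`, etc.

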
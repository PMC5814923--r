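---
title: "Methods: hydrological habitat occupancy from occurrence records and bioclimatic rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrological habitat occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroniche)
```

## The analysis

`hydroniche` estimates, for each species in a set of georeferenced presence
records, the *position* and *range* of its hydrological habitat occupancy,
and then tests how those quantities relate to each other, to geographic
range size, and to diversity within genera. The unit of observation is a
species; the raw material is a table of presence points and a stack of six
co-registered bioclimatic rasters:

| Variable | Units | Meaning |
|---|---|---|
| MAP | mm | mean annual precipitation |
| P_dry | mm | precipitation of the driest month |
| P_seas | % | precipitation seasonality (CV-style percentage) |
| AET, PET | mm | actual / potential evapotranspiration |
| AI | — | aridity index, stored as the scaled integer `round(10^4 * MAP / PET)` |

Five indicators enter every downstream analysis: MAP, AI, AET/PET (the
per-point ratio), P_dry and P_seas. For a species with points
$x_1,\dots,x_n$ and indicator values $v(x_i)$, the univariate **habitat
position** is $\bar v$ and the **habitat range** is
$\max_i v(x_i) - \min_i v(x_i)$ — a deliberately simple, assumption-free
breadth proxy. The pipeline is: clean records, extract values, summarize
per species, build PCA climate spaces, compute within-group interval
overlaps, measure geodesic range areas, and run the regression/ANOVA
batteries.

## Record cleaning

Presence data of herbarium provenance carry three well-known error classes,
which are removed in a fixed order so that report counts are unambiguous:

1. **Duplicates** within species: identical coordinates after rounding to
   4 decimal places (~11 m). The first record in `record_id` sort order is
   kept, which also makes the output invariant to input row order.
2. **Institution records**: points within `institution_tolerance_deg`
   (default 0.001°, ~100 m, absorbing coordinate rounding at collection
   addresses) of any blocklisted herbarium / living-collection coordinate.
3. **Out-of-native-range records**: points outside the species'
   axis-aligned native box. The judgement "obviously outside the native
   range" cannot be automated without an explicit operationalization; the
   boxes are that operationalization, and a species without a box skips
   this rule with a logged warning rather than failing.

Species retaining fewer than `min_points = 3` records are excluded
entirely: with two points or fewer, a range estimate is degenerate. The
per-species report satisfies
`n_input = n_retained + n_dup + n_inst + n_outside` by construction, and
cleaning is idempotent.

## Extraction conventions

Grids are north-up with half-open cells: a point on a cell's western or
northern edge belongs to that cell (`floor((lon - origin_lon)/cell_size)`,
0-based). AET/PET is computed **per point** and then summarized, rather
than as a ratio of species-mean AET to species-mean PET: the layers are
co-registered, the ratio is a per-location water supply/demand proxy, and
per-point computation keeps its min/max meaningful. Cells with PET = 0 are
nodata for the ratio. Points outside the grid or on nodata in any
indicator are dropped and counted.

The collinearity screen regresses every indicator pair across species
means, linearly and quadratically, and reports the larger r². "Non-linear"
is implemented as a quadratic polynomial because no specific family is
canonical for this screen; the choice only affects flagging sensitivity,
not any downstream computation. The default flag threshold is r² = 0.70.

## PCA climate spaces

Species-level values are transformed as `log10(x + 1)` — the offset is
required because dry-month precipitation and range values can be exactly 0
— then centred and scaled to unit variance before PCA. Scaling to the
correlation matrix is forced by the heterogeneous units (mm, %, scaled
integers). PCA signs are arbitrary, so each component is flipped, if
needed, to make its largest-magnitude loading positive; score plots are
then reproducible across platforms. The *position* space uses the five
`*_mean` columns, the *range* space the five `*_range` columns.

Genus-level diversity in either space is the area of the convex hull of
the genus's species scores in PC1–PC2, for genera with at least three
species (two points have zero hull area by definition, so the threshold
mirrors the cleaning rule). Hull vertices come from `grDevices::chull`;
the area is the shoelace formula. Tests verify hulls against an
exhaustive O(n³) edge-enumeration oracle.

## Interval overlap and its normalization

For one indicator and one group, the overlap of species *i* and *j* is

$$\omega_{ij} = \max\!\big(0,\ \min(\max_i, \max_j) - \max(\min_i, \min_j)\big),$$

the length of the intersection of the two habitat intervals, in the
variable's units. The group statistic is the mean (and SD) of
$\omega_{ij}$ over the distinct unordered pairs $i<j$, normalized by the
group's mean species-level range. The diagonal (a species' own range) is
**excluded** from the mean: including it would mix within-species ranges
into a between-species overlap statistic, and with the pairs-only mean the
normalized overlap is provably in [0, 1], because each $\omega_{ij}$ is
bounded by the smaller of the two ranges. Whether the original statistic
included the diagonal is not decidable from its printed values alone, so
the choice is exposed as `include_diagonal = TRUE` for sensitivity
analysis. By default only AI and P_seas are analysed; the remaining
indicators are strongly collinear with these, so univariate overlap on
them is largely redundant.

The published group-level table ships with the package
(`reference_overlap_table()`); its normalization column reproduces from
its printed overlap and mean-range columns to all three printed decimals,
which the test suite and acceptance script verify.

## Geographic range size

The extent of occurrence is the convex hull of a species' points fitted in
geographic (lon/lat) coordinates — the convention of desktop-GIS hull
tools — with its area evaluated as a geodesic polygon on the WGS84
ellipsoid and reported in km². Collinear or fewer-than-three-point species
get a degenerate flag and zero area. Antimeridian-spanning hulls are
rejected explicitly; no study species requires them. Tests compare the
geodesic area against an independently coded spherical-excess (l'Huilier)
computation on the authalic sphere; the two differ by ~0.45% for a 1°×1°
equatorial quadrilateral, within the expected sphere-vs-ellipsoid
discrepancy.

## Hypothesis batteries

* **Position vs range**, per indicator, on untransformed values.
* **log₁₀(area + 1) vs indicator range** for the five indicators.
* **Richness and diversity** across genera with ≥3 scored species:
  log₁₀ richness vs log₁₀ hull area in position space and in range space,
  plus position-space vs range-space hull areas (untransformed).
* **One-way ANOVA** of log₁₀(area + 1) across functional types. The log
  scale is used because extent-of-occurrence distributions are
  heavy-tailed; this is a documented choice, as the original scale is not
  stated for this comparison.
* **Sensitivity screen**: Pearson correlation of the per-species usable
  point count with each indicator's range. When sample size is constant
  by design (as in the bundled simulation), the correlation is undefined
  and reported as missing.

All logs are `log10(v + 1)` throughout, for consistency with the PCA
transform. No multiple-testing correction is applied; p values are
reported raw, matching standard practice for these descriptive batteries.

## The synthetic study system

Real inputs for this analysis are a snapshot of an occurrence aggregator
and ~30 arc-second global rasters, neither of which can be bundled or
regenerated. The package therefore includes a first-class generator whose
statistical structure matches what the analysis assumes, with known truth
for every stage:

* **Climate fields.** Each layer is uniform noise smoothed with a Gaussian
  kernel (`smoothing_length_cells` standard deviations of spatial
  autocorrelation), affinely rescaled to
  `[base - amplitude, base + amplitude]` and clamped. Variables share two
  latent fields: an overall-moisture block (MAP, AET, and PET with a
  *negative* loading — wet regions have lower evaporative demand, which
  also makes the derived AI strongly collinear with MAP, as observed in
  real layers) and a seasonality block (P_seas, with P_dry loading
  negatively). `cross_block_correlation` sets the correlation between the
  two latents; `block_weight` (default 0.7) sets how much of each
  variable is block-shared versus variable-specific. AI is derived
  cell-wise as `round(10^4 * MAP / PET)`. Defaults
  (`default_field_specs()`) use Neotropical-scale magnitudes — MAP
  1800 ± 1600 mm, P_dry 60 ± 60 mm, P_seas 60 ± 45 %, AET 1000 ± 500 mm,
  PET 1500 ± 500 mm (clamped ≥ 300 mm so AI is defined everywhere) — and
  a smoothing length of 8 cells on a 120×120, 0.05° grid.
* **Species.** A niche is a product of Gaussian kernels,
  $\exp(-(v - \mu_v)^2 / 2\sigma_v^2)$ over one or more variables; cells
  are sampled with probability proportional to suitability and points
  placed uniformly within the cell (plus optional jitter). Each species
  draws from its own RNG sub-stream derived by hashing its id, so results
  are independent of species insertion order. A niche whose kernel is
  numerically zero everywhere on the landscape (every cell more than ~38σ
  from the optimum) is an error naming the species.
* **Contaminants.** `inject_contaminants()` appends exactly the three
  record classes the cleaning stage removes, with per-record truth labels.

What the generator does **not** emulate: real Neotropical geography,
temperature variables, spatially biased collection effort, georeferencing
error beyond uniform jitter, and taxonomic misidentification. Passing
tests therefore demonstrate the pipeline's correctness and the
recoverability of known structure — not that any real dataset is free of
those problems.

### The study cohort, and why it is gradient-dominated

`simulate_study_cohort()` defines the simulation used for parameter
recovery and for the range-size association study: 50 species × 100
points, bivariate niches on MAP and P_seas (one variable from each latent
block) with a single per-species breadth scale factor spread over
0.05–0.5 of each variable's landscape range, optima drawn uniformly from
the central 20–80% band, and smoothing length 40 cells — i.e. fields that
vary smoothly at the scale of the whole region, as continental
precipitation gradients do.

The long correlation length is essential to the cohort's logic, which
requires that *niche breadth drives spatial spread*. On a
short-correlation (patchy) landscape, the cells matching a narrow climate
band form thin iso-contours scattered across the entire region: a
specialist's convex hull is then nearly as large as a generalist's, spread
decouples from breadth, and breadth recovery degrades (we measure
Spearman ρ ≈ 0.7 there, versus ≈ 0.8–0.9 on the gradient landscape).
Likewise the bivariate niche matters: constraining only MAP leaves species
unconfined along the seasonality gradient, so dry-month precipitation
ranges barely respond to breadth. Both behaviours are real properties of
niche-based sampling, worth knowing when interpreting occurrence data
from topographically complex regions; the cohort deliberately represents
the gradient-dominated regime that the downstream hypotheses presuppose.
The negative control re-samples species at one fixed spatial extent each,
which severs the breadth–spread link and should (and does) erase the
range-size associations.

## Numerical choices and degenerate inputs

* Seeded determinism everywhere: every generator is a pure function of its
  spec including the seed; RNG state of the caller is restored.
* Duplicate rounding at 4 dp; institution match radius Euclidean in
  degrees; both configurable.
* Zero-variance variables: an error in PCA (named), an undefined (NA) pair
  in the collinearity screen, a missing regression result, and a missing
  normalized overlap when a group's mean range is 0.
* Degenerate hulls (collinear, <3 unique points) have zero area and a
  flag, not an error.
* The sampled-value mean equals the niche optimum only when the
  landscape's availability density is symmetric around it; on a skewed
  availability the mean shifts by roughly $\sigma^2 \,
  \mathrm{d}\log f/\mathrm{d}v$ — a property of suitability-weighted
  sampling, not an implementation artefact.

## Problem sizes

The bundled analysis and the test suite run the cohort at 50 species ×
100 points on a 120×120 grid, 1000-replicate null simulations for the
ANOVA size check, 1000 random groups for the overlap oracle, and
100-replicate negative controls — sizes chosen so the full suite completes
in well under a minute while keeping Monte-Carlo noise far from the
assertion margins.

## Known limitations

* Habitat range (max − min) is sensitive to single extreme records;
  cleaning mitigates but cannot remove this.
* Extent-of-occurrence hulls ignore land/sea and habitat suitability, as
  the underlying convention does.
* The overlap statistic is univariate by design; it does not measure
  multivariate niche overlap.
* The collinearity screen's quadratic family is one of several reasonable
  "non-linear" choices.
* On strongly patchy landscapes, breadth–spread coupling weakens (see
  above); conclusions drawn from the cohort apply to the
  gradient-dominated regime.
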
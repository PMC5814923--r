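#' Simulate the standard niche-breadth study cohort
#'
#' Builds the simulation cohort used by the package's parameter-recovery and
#' range-size association studies: a gradient-dominated landscape (long
#' smoothing lengths, so each climate field varies smoothly at the scale of
#' the whole region, as continental precipitation gradients do) and species
#' whose niches are bivariate Gaussian kernels on one variable from each
#' latent block (MAP for overall moisture, P_seas for seasonality), with a
#' single breadth scale factor per species applied to both variables. Under
#' this design a species' climatic tolerance controls the size of its
#' occupied climate band in both gradient directions, so niche breadth
#' drives spatial spread — the causal structure whose downstream signatures
#' (breadth recovered as habitat range; geographic range size increasing
#' with habitat range) the analysis is meant to detect. On patchy,
#' short-correlation landscapes a narrow climate band instead forms
#' scattered iso-contours spanning the whole region, and spatial spread
#' decouples from breadth; see the methods vignette.
#'
#' @param seed Integer seed controlling landscape, optima and sampling.
#' @param n_species Number of species (default 50).
#' @param n_points Presence points per species (default 100).
#' @param breadth_scales Range of per-species breadth scale factors, as
#'   fractions of each niche variable's landscape value range; scales are
#'   spread evenly across species (default 0.05 to 0.5, a tenfold span).
#' @param smoothing_length_cells Smoothing length of every climate field in
#'   cells (default 40 on the default 120-cell grid, i.e. one third of the
#'   region: gradient-dominated).
#' @param optimum_band Quantile-like band (fractions of each variable's
#'   value range) within which species optima are drawn uniformly
#'   (default 0.2 to 0.8, keeping kernels mostly on-landscape).
#' @return List: \code{stack}, \code{occurrences}, \code{truth} (specified
#'   optima and breadths per species), \code{niches}.
#' @export
simulate_study_cohort <- function(seed = 7L, n_species = 50L, n_points = 100L,
                                  breadth_scales = c(0.05, 0.5),
                                  smoothing_length_cells = 40,
                                  optimum_band = c(0.2, 0.8)) {
  fs <- default_field_specs()
  for (v in names(fs)) fs[[v]]$smoothing_length_cells <- smoothing_length_cells
  stack <- generate_climate_stack(landscape_spec(fields = fs, seed = seed))
  map <- range(stack$layers$MAP)
  ps <- range(stack$layers$P_seas)
  scales <- seq(breadth_scales[1], breadth_scales[2], length.out = n_species)
  niches <- with_seed(derive_seed(seed, "cohort_optima"), {
    om <- stats::runif(n_species, map[1] + optimum_band[1] * diff(map),
                       map[1] + optimum_band[2] * diff(map))
    op <- stats::runif(n_species, ps[1] + optimum_band[1] * diff(ps),
                       ps[1] + optimum_band[2] * diff(ps))
    lapply(seq_len(n_species), function(i) {
      niche_spec(sprintf("sp%03d", i),
                 optima = c(MAP = om[i], P_seas = op[i]),
                 breadth_sigma = c(MAP = scales[i] * diff(map),
                                   P_seas = scales[i] * diff(ps)),
                 n_points = n_points)
    })
  })
  g <- generate_species_occurrences(stack, niches, seed = seed)
  list(stack = stack, occurrences = g$occurrences, truth = g$truth,
       niches = niches)
}
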
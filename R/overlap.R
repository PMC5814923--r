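#' Pairwise interval-overlap matrix for one group
#'
#' For every pair of species in a group, the overlap of their habitat
#' intervals on one indicator variable:
#' \code{max(0, min(max_i, max_j) - max(min_i, min_j))}, in the variable's
#' units. The matrix is symmetric and its diagonal equals each species' own
#' range (\code{max - min}).
#'
#' @param summaries Species summary table (rows of one taxonomic group) with
#'   \code{<variable>_min} and \code{<variable>_max} columns.
#' @param variable Indicator name (e.g. \code{"AI"} or \code{"P_seas"}).
#' @return Symmetric numeric matrix with species names on both dimensions.
#' @export
pairwise_overlap_matrix <- function(summaries, variable) {
  lo <- summaries[[paste0(variable, "_min")]]
  hi <- summaries[[paste0(variable, "_max")]]
  if (is.null(lo) || is.null(hi)) {
    stop("summaries lack min/max columns for ", variable, call. = FALSE)
  }
  if (length(lo) < 2) stop("need >= 2 species", call. = FALSE)
  if (any(lo > hi)) {
    stop("min > max for species: ",
         paste(summaries$species[lo > hi], collapse = ", "), call. = FALSE)
  }
  m <- outer(hi, hi, pmin) - outer(lo, lo, pmax)
  m[m < 0] <- 0
  dimnames(m) <- list(summaries$species, summaries$species)
  m
}

#' Group-level overlap summary with range normalization
#'
#' Reduces a pairwise overlap matrix to the group statistics: mean and
#' standard deviation of the overlap over the distinct (unordered,
#' off-diagonal) species pairs, the group's mean species-level range, and
#' the normalized overlap (mean overlap divided by mean range). With the
#' off-diagonal-pairs mean, normalized overlap always lies in [0, 1], since
#' each pair's overlap is bounded by the smaller of the two ranges. Setting
#' \code{include_diagonal = TRUE} instead averages over the full matrix
#' (species' own ranges included), for sensitivity checks.
#'
#' @param m Matrix from \code{\link{pairwise_overlap_matrix}}.
#' @param summaries The same group's summary rows.
#' @param variable Indicator name the matrix was built on.
#' @param group Group label carried into the output.
#' @param include_diagonal Average over the full matrix rather than the
#'   distinct off-diagonal pairs (default FALSE).
#' @return One-row data.frame: \code{group}, \code{variable},
#'   \code{n_species}, \code{mean_pairwise_overlap},
#'   \code{sd_pairwise_overlap}, \code{mean_species_range},
#'   \code{normalized_overlap} (NA when the mean range is 0).
#' @export
group_overlap_summary <- function(m, summaries, variable, group = NA_character_,
                                  include_diagonal = FALSE) {
  vals <- if (include_diagonal) as.vector(m) else m[upper.tri(m)]
  rng <- summaries[[paste0(variable, "_max")]] -
    summaries[[paste0(variable, "_min")]]
  mean_range <- mean(rng)
  mo <- mean(vals)
  data.frame(group = group, variable = variable, n_species = nrow(m),
             mean_pairwise_overlap = mo,
             sd_pairwise_overlap = stats::sd(vals),
             mean_species_range = mean_range,
             normalized_overlap = if (mean_range > 0) mo / mean_range else NA_real_,
             stringsAsFactors = FALSE)
}

#' Overlap table across groups and indicator variables
#'
#' Applies \code{\link{pairwise_overlap_matrix}} and
#' \code{\link{group_overlap_summary}} to every group with at least two
#' species, for each requested indicator. By default only AI and P_seas are
#' used: the remaining indicators are strongly collinear with these, so
#' univariate overlap on them adds little.
#'
#' @param summaries Species summary table.
#' @param groups Data.frame \code{species}, \code{group}.
#' @param variables Indicators to analyse (default \code{c("AI", "P_seas")}).
#' @param include_diagonal Passed through to
#'   \code{\link{group_overlap_summary}}.
#' @return Data.frame with one row per group x variable.
#' @export
overlap_table <- function(summaries, groups, variables = c("AI", "P_seas"),
                          include_diagonal = FALSE) {
  merged <- merge(summaries, groups, by = "species")
  rows <- list()
  for (g in sort(unique(merged$group))) {
    d <- merged[merged$group == g, , drop = FALSE]
    if (nrow(d) < 2) next
    for (v in variables) {
      m <- pairwise_overlap_matrix(d, v)
      rows[[length(rows) + 1L]] <-
        group_overlap_summary(m, d, v, group = g,
                              include_diagonal = include_diagonal)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Published group-overlap reference statistics
#'
#' The published group-level overlap statistics for terrestrial bromeliad
#' taxonomic groups (aridity index and precipitation seasonality): mean
#' pairwise overlap, mean species-level range, and their ratio as printed.
#' Shipped for arithmetic self-consistency checks of the normalization.
#'
#' @return Data.frame \code{group}, \code{n}, \code{variable},
#'   \code{overlap}, \code{mean_range}, \code{overlap_over_mean}.
#' @export
reference_overlap_table <- function() {
  path <- system.file("extdata", "overlap_reference.csv",
                      package = "hydroniche", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
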
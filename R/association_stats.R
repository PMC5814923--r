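#' Ordinary least-squares regression with optional log10 transforms
#'
#' Fits \code{y ~ x} by OLS after optionally transforming either axis as
#' \code{log10(v + 1)} (the offset accommodates exact zeros in ranges and
#' areas). r-squared is the squared Pearson correlation of the transformed
#' axes; the p value is the two-sided t test on the slope.
#'
#' @param x,y Numeric vectors of equal length.
#' @param log_x,log_y Apply the log10(v + 1) transform to that axis.
#' @param label Label carried into the result row.
#' @return One-row data.frame: \code{label}, \code{n}, \code{slope},
#'   \code{intercept}, \code{r2}, \code{p_value}, \code{sign} (\code{"+"} or
#'   \code{"-"}), \code{log_x}, \code{log_y}. All-NA statistics when n < 3
#'   or x has zero variance (reported as missing, not an error).
#' @export
linear_regression <- function(x, y, log_x = FALSE, log_y = FALSE, label = "") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (log_x) x <- log10(x + 1)
  if (log_y) y <- log10(y + 1)
  miss <- data.frame(label = label, n = length(x), slope = NA_real_,
                     intercept = NA_real_, r2 = NA_real_, p_value = NA_real_,
                     sign = NA_character_, log_x = log_x, log_y = log_y,
                     stringsAsFactors = FALSE)
  if (length(x) < 3 || stats::sd(x) == 0) return(miss)
  if (stats::sd(y) == 0) {
    miss$slope <- 0; miss$intercept <- y[1]; miss$r2 <- 0
    miss$p_value <- 1; miss$sign <- "+"
    return(miss)
  }
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  data.frame(label = label, n = length(x), slope = slope,
             intercept = co["(Intercept)", "Estimate"],
             r2 = summary(fit)$r.squared,
             p_value = co["x", "Pr(>|t|)"],
             sign = if (slope >= 0) "+" else "-",
             log_x = log_x, log_y = log_y, stringsAsFactors = FALSE)
}

#' One-way fixed-effects analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector of the same length. Groups with
#'   fewer than two values are excluded with a warning.
#' @return List: \code{F}, \code{p}, \code{group_means},
#'   \code{group_sizes}, \code{df} (numerator, denominator).
#' @export
anova_oneway <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("groups with < 2 values excluded: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2) stop("need >= 2 groups with >= 2 values", call. = FALSE)
  fit <- stats::lm(values ~ factor(groups))
  an <- stats::anova(fit)
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       group_means = tapply(values, groups, mean),
       group_sizes = as.vector(sizes),
       df = c(an$Df[1], an$Df[2]))
}

#' Run the full association-hypothesis battery
#'
#' Executes the standard set of tests linking habitat position, habitat
#' range, geographic range size and genus-level diversity:
#' \describe{
#'   \item{position_vs_range}{per indicator, OLS of species habitat range on
#'     habitat position (both untransformed) — do species in more extreme
#'     (e.g. arid) positions have narrower ranges?}
#'   \item{georange_vs_habitat_range}{per indicator, OLS of
#'     log10(area_km2 + 1) on the species' indicator range — is climatic
#'     tolerance associated with larger geographic ranges?}
#'   \item{richness_diversity}{across genera with >= 3 species: log10
#'     richness vs log10 PC1-PC2 hull area in position space and in range
#'     space, plus position-space vs range-space hull area.}
#'   \item{anova}{one-way ANOVA of log10(area_km2 + 1) across functional
#'     types.}
#'   \item{sensitivity}{Pearson correlation of the per-species usable point
#'     count with each indicator's range (sample-size sensitivity screen).}
#' }
#' No multiple-testing correction is applied; p values are raw.
#'
#' @param summaries Species summary table.
#' @param georanges Output of \code{\link{species_georanges}}.
#' @param genera Data.frame \code{species}, \code{group} (genus) for the
#'   diversity regressions.
#' @param functional_types Data.frame \code{species}, \code{functional_type}.
#' @param richness Data.frame \code{group}, \code{richness} (species counts
#'   per genus); genera missing from it are dropped with a warning.
#' @param spaces Optional list with elements \code{position} and
#'   \code{range} (\code{habitat_space} objects); fitted from
#'   \code{summaries} when NULL.
#' @param min_species Minimum species per genus for hulls (default 3).
#' @return A \code{hypothesis_report} list with elements
#'   \code{position_vs_range}, \code{georange_vs_habitat_range},
#'   \code{richness_diversity}, \code{anova}, \code{sensitivity},
#'   \code{hulls}.
#' @export
run_hypothesis_battery <- function(summaries, georanges, genera,
                                   functional_types, richness,
                                   spaces = NULL, min_species = 3) {
  merged <- merge(summaries, georanges, by = "species")

  h4 <- do.call(rbind, lapply(HYDRO_INDICATORS, function(v) {
    linear_regression(merged[[paste0(v, "_mean")]],
                      merged[[paste0(v, "_range")]], label = v)
  }))

  h5 <- do.call(rbind, lapply(HYDRO_INDICATORS, function(v) {
    linear_regression(merged[[paste0(v, "_range")]], merged$area_km2,
                      log_y = TRUE, label = v)
  }))

  if (is.null(spaces)) {
    spaces <- list(position = fit_habitat_space(summaries, "position"),
                   range = fit_habitat_space(summaries, "range"))
  }
  hp <- group_hull_area(spaces$position, genera, min_species)
  hr <- group_hull_area(spaces$range, genera, min_species)
  hulls <- merge(hp[, c("group", "n_species", "hull_area")],
                 hr[, c("group", "hull_area")],
                 by = "group", suffixes = c("_position", "_range"))
  no_rich <- setdiff(hulls$group, richness$group)
  if (length(no_rich) > 0) {
    warning("no richness value for: ", paste(no_rich, collapse = ", "))
  }
  hull_rich <- merge(hulls, richness, by = "group")
  h6 <- rbind(
    linear_regression(hull_rich$hull_area_position, hull_rich$richness,
                      log_x = TRUE, log_y = TRUE,
                      label = "richness_vs_position_diversity"),
    linear_regression(hull_rich$hull_area_range, hull_rich$richness,
                      log_x = TRUE, log_y = TRUE,
                      label = "richness_vs_range_diversity"),
    linear_regression(hulls$hull_area_position, hulls$hull_area_range,
                      label = "position_vs_range_diversity"))

  ft <- merge(georanges, functional_types, by = "species")
  av <- anova_oneway(log10(ft$area_km2 + 1), ft$functional_type)

  sens <- do.call(rbind, lapply(HYDRO_INDICATORS, function(v) {
    np <- summaries$n_points_used
    rng <- summaries[[paste0(v, "_range")]]
    if (stats::sd(np) == 0 || stats::sd(rng) == 0) {
      return(data.frame(variable = v, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(np, rng)
    data.frame(variable = v, r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))

  structure(list(position_vs_range = h4,
                 georange_vs_habitat_range = h5,
                 richness_diversity = h6,
                 anova = av, sensitivity = sens, hulls = hulls),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Habitat position vs range (per indicator):\n")
  print(x$position_vs_range, digits = 3)
  cat("\nlog10 geographic range size vs indicator range:\n")
  print(x$georange_vs_habitat_range, digits = 3)
  cat("\nGenus richness and habitat diversity:\n")
  print(x$richness_diversity, digits = 3)
  cat(sprintf("\nANOVA of log10 range size across functional types: F = %.3f, p = %.3f\n",
              x$anova$F, x$anova$p))
  cat("\nSample-size sensitivity (r of n_points with range):\n")
  print(x$sensitivity, digits = 3)
  invisible(x)
}
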
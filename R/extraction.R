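#' Extract bioclimatic values at occurrence points
#'
#' Looks up, for each record, the value of every climate-stack layer at the
#' grid cell containing the point. The grid is north-up with half-open
#' cells: column index \code{floor((lon - origin_lon) / cell_size)}, row
#' index \code{floor((origin_lat - lat) / cell_size)} (0-based), so a point
#' exactly on a cell's western/northern edge belongs to that cell. The
#' ratio AET/PET is computed per point; cells with PET = 0 are treated as
#' nodata for the ratio. Points outside the grid, or on nodata in any
#' indicator layer, are dropped and counted.
#'
#' @param stack A \code{climate_stack}.
#' @param records Occurrence data.frame (\code{species}, \code{longitude},
#'   \code{latitude}, \code{record_id}).
#' @return Data.frame with one row per usable record: the record columns
#'   plus MAP, P_dry, P_seas, AET, PET, AI, AET_PET. Attribute
#'   \code{"drop_log"} holds \code{n_outside} and \code{n_nodata}.
#' @export
extract_values <- function(stack, records) {
  stopifnot(inherits(stack, "climate_stack"))
  col0 <- floor((records$longitude - stack$origin_lon) / stack$cell_size)
  row0 <- floor((stack$origin_lat - records$latitude) / stack$cell_size)
  inside <- col0 >= 0 & col0 < stack$n_cols & row0 >= 0 & row0 < stack$n_rows
  n_outside <- sum(!inside)
  out <- records[inside, , drop = FALSE]
  col0 <- col0[inside]
  row0 <- row0[inside]
  idx <- cbind(row0 + 1L, col0 + 1L)
  for (v in names(stack$layers)) out[[v]] <- stack$layers[[v]][idx]
  pet <- out$PET
  pet[!is.na(pet) & pet == 0] <- NA_real_
  out$AET_PET <- out$AET / pet
  usable <- stats::complete.cases(out[, HYDRO_INDICATORS, drop = FALSE])
  n_nodata <- sum(!usable)
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- list(n_outside = n_outside, n_nodata = n_nodata)
  out
}

#' Summarize per-point values to species habitat position and range
#'
#' For each species with at least \code{min_points} usable points, computes
#' the arithmetic mean (habitat position), minimum, maximum and range
#' (max - min, habitat range) of each of the five indicators. Species below
#' the threshold are excluded (mirroring the minimum-presence-point
#' inclusion rule) and listed in the \code{"excluded_species"} attribute.
#'
#' @param values Per-point value table from \code{\link{extract_values}}.
#' @param min_points Minimum usable points per species (default 3).
#' @return Data.frame with columns \code{species}, \code{n_points_used} and,
#'   per indicator V, \code{V_mean}, \code{V_min}, \code{V_max},
#'   \code{V_range}.
#' @export
summarize_species <- function(values, min_points = 3) {
  sp <- split(values, values$species)
  rows <- lapply(sp, function(d) {
    out <- data.frame(species = d$species[1], n_points_used = nrow(d),
                      stringsAsFactors = FALSE)
    for (v in HYDRO_INDICATORS) {
      x <- d[[v]]
      out[[paste0(v, "_mean")]] <- mean(x)
      out[[paste0(v, "_min")]] <- min(x)
      out[[paste0(v, "_max")]] <- max(x)
      out[[paste0(v, "_range")]] <- max(x) - min(x)
    }
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  excluded <- res$species[res$n_points_used < min_points]
  if (length(excluded) > 0) {
    warning("excluded (fewer than ", min_points, " usable points): ",
            paste(excluded, collapse = ", "))
  }
  res <- res[res$n_points_used >= min_points, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded_species") <- excluded
  res
}

#' Pairwise collinearity screen over species-mean indicators
#'
#' For every pair of indicators, fits a linear and a quadratic regression of
#' one species-mean on the other and reports the larger r-squared. Pairs
#' exceeding \code{threshold} are flagged; a zero-variance variable makes
#' its pairs undefined (NA) rather than an error.
#'
#' @param summaries Species summary table from
#'   \code{\link{summarize_species}}.
#' @param threshold Flagging threshold on max r-squared (default 0.70).
#' @return List with \code{r2} (symmetric 5 x 5 matrix of
#'   max(linear, quadratic) r-squared) and \code{flagged} (data.frame of
#'   pairs above threshold).
#' @export
variable_collinearity_screen <- function(summaries, threshold = 0.70) {
  if (nrow(summaries) < 3) stop("need >= 3 species", call. = FALSE)
  vars <- HYDRO_INDICATORS
  means <- summaries[, paste0(vars, "_mean"), drop = FALSE]
  names(means) <- vars
  r2 <- matrix(NA_real_, 5, 5, dimnames = list(vars, vars))
  diag(r2) <- 1
  for (i in 1:4) for (j in (i + 1):5) {
    x <- means[[vars[i]]]
    y <- means[[vars[j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r2_lin <- summary(stats::lm(y ~ x))$r.squared
    r2_quad <- summary(stats::lm(y ~ x + I(x^2)))$r.squared
    r2[i, j] <- r2[j, i] <- max(r2_lin, r2_quad)
  }
  pairs <- which(upper.tri(r2) & r2 > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                        r2 = r2[pairs], stringsAsFactors = FALSE)
  list(r2 = r2, flagged = flagged)
}
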
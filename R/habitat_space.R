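#' Fit a multivariate habitat space by PCA
#'
#' Builds the climate space on species-level indicator summaries: values are
#' transformed as \code{log10(x + log_offset)} per variable (the offset
#' accommodates exact zeros in dry-month precipitation and in ranges),
#' centred and scaled to unit variance, and decomposed by PCA (equivalently,
#' an eigendecomposition of the correlation matrix of the transformed
#' values). Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making score plots reproducible.
#'
#' @param summaries Species summary table from
#'   \code{\link{summarize_species}}.
#' @param kind \code{"position"} uses the \code{*_mean} columns (habitat
#'   position space), \code{"range"} the \code{*_range} columns (habitat
#'   range space).
#' @param log_offset Offset inside the log10 transform (default 1).
#' @return A \code{habitat_space} object: \code{variables}, \code{kind},
#'   \code{log_offset}, \code{center}, \code{scale}, \code{loadings}
#'   (5 x K), \code{scores} (species x K), \code{variance_explained}
#'   (fractions summing to 1).
#' @export
fit_habitat_space <- function(summaries, kind = c("position", "range"),
                              log_offset = 1) {
  kind <- match.arg(kind)
  if (nrow(summaries) < 3) stop("need >= 3 species", call. = FALSE)
  suffix <- if (kind == "position") "_mean" else "_range"
  x <- as.matrix(summaries[, paste0(HYDRO_INDICATORS, suffix), drop = FALSE])
  colnames(x) <- HYDRO_INDICATORS
  rownames(x) <- summaries$species
  if (!all(is.finite(x))) stop("non-finite summary values", call. = FALSE)
  xt <- log10(x + log_offset)
  sds <- apply(xt, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero variance after transform in: ",
         paste(colnames(xt)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(xt, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(variables = HYDRO_INDICATORS, kind = kind,
                 log_offset = log_offset,
                 center = pc$center, scale = pc$scale,
                 loadings = pc$rotation, scores = pc$x,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "habitat_space")
}

#' @export
print.habitat_space <- function(x, ...) {
  cat(sprintf("habitat_space (%s): %d species, %d components\n",
              x$kind, nrow(x$scores), ncol(x$scores)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# Shoelace area of a polygon given (x, y) vertex matrix (open ring).
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Convex hull area of a 2-column point matrix (0 for degenerate sets).
hull_area_xy <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  shoelace_area(xy[h, , drop = FALSE])
}

#' Convex-hull area of each group's scores in PC1-PC2
#'
#' Measures the diversity of habitat position (or range) within each group
#' as the area of the smallest convex hull covering the group's species
#' scores on the first two components. Groups with fewer than
#' \code{min_species} scored species are omitted (listed in the
#' \code{"omitted_groups"} attribute).
#'
#' @param space A \code{habitat_space}.
#' @param groups Data.frame \code{species}, \code{group} (e.g. genus).
#' @param min_species Minimum species per group (default 3).
#' @return Data.frame \code{group}, \code{n_species}, \code{hull_area}
#'   (squared score units), \code{kind}.
#' @export
group_hull_area <- function(space, groups, min_species = 3) {
  stopifnot(inherits(space, "habitat_space"))
  sc <- space$scores[, 1:2, drop = FALSE]
  groups <- groups[groups$species %in% rownames(sc), , drop = FALSE]
  counts <- table(groups$group)
  keep <- names(counts)[counts >= min_species]
  omitted <- setdiff(names(counts), keep)
  rows <- lapply(keep, function(g) {
    sp <- groups$species[groups$group == g]
    data.frame(group = g, n_species = length(sp),
               hull_area = hull_area_xy(sc[sp, , drop = FALSE]),
               kind = space$kind, stringsAsFactors = FALSE)
  })
  res <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(0), n_species = integer(0),
               hull_area = numeric(0), kind = character(0))
  }
  attr(res, "omitted_groups") <- omitted
  res
}
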
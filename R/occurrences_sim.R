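#' Specification of a species' simulated hydrological niche
#'
#' The species' suitability over the landscape is a product of independent
#' Gaussian kernels, one per listed variable:
#' \code{exp(-(v_cell - optimum_v)^2 / (2 * breadth_sigma_v^2))}. Occurrence
#' cells are drawn with probability proportional to this suitability, so
#' \code{breadth_sigma} is the niche breadth on each variable's own scale.
#'
#' @param species_id Species name (nonempty string).
#' @param optima Named numeric vector of niche optima, in the variables'
#'   units; names must be climate-stack layer names.
#' @param breadth_sigma Named numeric vector (or single number recycled over
#'   \code{optima}) of kernel standard deviations, same units; all > 0.
#' @param n_points Target number of presence records (>= 1).
#' @param coordinate_jitter Uniform jitter (degrees) added to each
#'   within-cell point position, emulating georeferencing error.
#' @param seed Optional integer seed; if NULL, a sub-stream is derived from
#'   the sampling seed by stable hashing of \code{species_id}, making the
#'   generated points independent of species insertion order.
#' @return A \code{niche_spec} list.
#' @export
niche_spec <- function(species_id, optima, breadth_sigma, n_points,
                       coordinate_jitter = 0, seed = NULL) {
  check_that(is.character(species_id) && nzchar(species_id), "species_id",
             "must be a nonempty string")
  check_that(length(names(optima)) == length(optima) && all(nzchar(names(optima))),
             "optima", "must be a named vector")
  if (length(breadth_sigma) == 1L && is.null(names(breadth_sigma))) {
    breadth_sigma <- stats::setNames(rep(breadth_sigma, length(optima)), names(optima))
  }
  check_that(setequal(names(breadth_sigma), names(optima)), "breadth_sigma",
             "must be named like optima")
  check_that(all(breadth_sigma > 0), "breadth_sigma", "must be > 0")
  check_that(n_points >= 1, "n_points", "must be >= 1")
  check_that(coordinate_jitter >= 0, "coordinate_jitter", "must be >= 0")
  structure(list(species_id = species_id, optima = optima,
                 breadth_sigma = breadth_sigma[names(optima)],
                 n_points = as.integer(n_points),
                 coordinate_jitter = coordinate_jitter, seed = seed),
            class = "niche_spec")
}

#' Sample niche-constrained species occurrences from a climate stack
#'
#' For each species, grid cells are sampled (with replacement) with
#' probability proportional to the product-Gaussian suitability kernel of
#' its \code{\link{niche_spec}}; each sampled cell yields one point placed
#' uniformly within the cell, plus optional coordinate jitter. A truth table
#' records the specified optima and breadths for parameter-recovery tests.
#'
#' @param stack A \code{climate_stack}.
#' @param niches List of \code{\link{niche_spec}} objects.
#' @param seed Integer master seed for the operation; per-species sub-streams
#'   are derived by stable hashing of the species id.
#' @return List with \code{occurrences} (data.frame \code{species},
#'   \code{longitude}, \code{latitude}, \code{record_id}) and \code{truth}
#'   (one row per species: optima, breadths, n_points).
#' @export
generate_species_occurrences <- function(stack, niches, seed = 1L) {
  stopifnot(inherits(stack, "climate_stack"))
  if (inherits(niches, "niche_spec")) niches <- list(niches)
  occ <- list()
  truth <- list()
  for (ns in niches) {
    stopifnot(inherits(ns, "niche_spec"))
    vars <- names(ns$optima)
    missing_layers <- setdiff(vars, names(stack$layers))
    if (length(missing_layers) > 0) {
      stop("niche for '", ns$species_id, "' references unknown layers: ",
           paste(missing_layers, collapse = ", "), call. = FALSE)
    }
    log_w <- matrix(0, stack$n_rows, stack$n_cols)
    for (v in vars) {
      log_w <- log_w - (stack$layers[[v]] - ns$optima[[v]])^2 /
        (2 * ns$breadth_sigma[[v]]^2)
    }
    log_w[!is.finite(log_w) | is.na(log_w)] <- -Inf
    # kernel mass numerically zero on every cell: the niche cannot be
    # realized on this landscape (log of the smallest normal double ~ -708)
    if (max(log_w) < log(.Machine$double.xmin)) {
      stop("suitability kernel has zero mass over the landscape for species: ",
           ns$species_id, call. = FALSE)
    }
    w <- exp(log_w - max(log_w))
    sp_seed <- if (!is.null(ns$seed)) ns$seed else derive_seed(seed, ns$species_id)
    pts <- with_seed(sp_seed, {
      idx <- sample.int(length(w), ns$n_points, replace = TRUE, prob = as.vector(w))
      row <- (idx - 1L) %% stack$n_rows + 1L
      col <- (idx - 1L) %/% stack$n_rows + 1L
      lon <- stack$origin_lon + (col - 1 + stats::runif(ns$n_points)) * stack$cell_size
      lat <- stack$origin_lat - (row - 1 + stats::runif(ns$n_points)) * stack$cell_size
      if (ns$coordinate_jitter > 0) {
        lon <- lon + stats::runif(ns$n_points, -ns$coordinate_jitter, ns$coordinate_jitter)
        lat <- lat + stats::runif(ns$n_points, -ns$coordinate_jitter, ns$coordinate_jitter)
      }
      data.frame(species = ns$species_id, longitude = lon, latitude = lat,
                 record_id = sprintf("%s_%05d", ns$species_id, seq_len(ns$n_points)),
                 stringsAsFactors = FALSE)
    })
    occ[[ns$species_id]] <- pts
    tr <- data.frame(species = ns$species_id, n_points = ns$n_points,
                     stringsAsFactors = FALSE)
    for (v in vars) {
      tr[[paste0(v, "_optimum")]] <- ns$optima[[v]]
      tr[[paste0(v, "_breadth")]] <- ns$breadth_sigma[[v]]
    }
    truth[[ns$species_id]] <- tr
  }
  occurrences <- do.call(rbind, c(occ, list(make.row.names = FALSE)))
  truth_tab <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  list(occurrences = occurrences, truth = truth_tab)
}

#' Sample occurrences at a fixed spatial extent, ignoring the niche
#'
#' Negative-control generator: each species receives points drawn uniformly
#' from one randomly placed square window of fixed side length, so spatial
#' spread (and hence geographic range area) is decoupled from climatic niche
#' breadth. Used to show that range-size/habitat-range associations are not
#' an artefact of the analysis pipeline.
#'
#' @param stack A \code{climate_stack} (defines the admissible region).
#' @param species_ids Character vector of species names.
#' @param n_points Points per species.
#' @param extent_deg Side length (degrees) of the fixed sampling window.
#' @param seed Integer master seed; per-species sub-streams by stable hash.
#' @return Occurrence data.frame (\code{species}, \code{longitude},
#'   \code{latitude}, \code{record_id}).
#' @export
sample_fixed_extent_occurrences <- function(stack, species_ids, n_points,
                                            extent_deg, seed = 1L) {
  stopifnot(inherits(stack, "climate_stack"))
  width <- stack$n_cols * stack$cell_size
  height <- stack$n_rows * stack$cell_size
  check_that(extent_deg > 0 && extent_deg <= min(width, height), "extent_deg",
             "must be positive and fit inside the landscape")
  out <- lapply(species_ids, function(sp) {
    with_seed(derive_seed(seed, sp), {
      x0 <- stack$origin_lon + stats::runif(1, 0, width - extent_deg)
      y1 <- stack$origin_lat - stats::runif(1, 0, height - extent_deg)
      data.frame(species = sp,
                 longitude = stats::runif(n_points, x0, x0 + extent_deg),
                 latitude = stats::runif(n_points, y1 - extent_deg, y1),
                 record_id = sprintf("%s_%05d", sp, seq_len(n_points)),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Specification of occurrence-record contamination
#'
#' Describes the three classes of erroneous record that occurrence-data
#' quality control must remove: exact duplicates, records at the coordinates
#' of herbaria or living collections, and records displaced outside the
#' species' native region. Counts apply per species.
#'
#' @param n_duplicates Exact-copy records appended per species (>= 0).
#' @param institution_points Two-column matrix or data.frame of (lon, lat)
#'   decoy coordinates; required nonempty when \code{n_institution} > 0.
#' @param n_institution Records per species placed exactly at institution
#'   coordinates (>= 0).
#' @param n_out_of_range Records per species displaced into a disjoint
#'   region outside the species' native box (>= 0).
#' @param seed Integer seed.
#' @return A \code{contamination_spec} list.
#' @export
contamination_spec <- function(n_duplicates = 0, institution_points = NULL,
                               n_institution = 0, n_out_of_range = 0,
                               seed = 1L) {
  check_that(n_duplicates >= 0 && n_institution >= 0 && n_out_of_range >= 0,
             "counts", "must all be >= 0")
  if (n_institution > 0) {
    check_that(!is.null(institution_points) && nrow(institution_points) > 0,
               "institution_points", "must be nonempty when n_institution > 0")
  }
  if (!is.null(institution_points)) {
    institution_points <- as.data.frame(institution_points)
    names(institution_points)[1:2] <- c("longitude", "latitude")
  }
  structure(list(n_duplicates = as.integer(n_duplicates),
                 institution_points = institution_points,
                 n_institution = as.integer(n_institution),
                 n_out_of_range = as.integer(n_out_of_range),
                 seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Inject labelled contaminant records into an occurrence set
#'
#' Appends, per species, exact duplicates of existing records, records at
#' institution decoy coordinates, and records displaced outside the species'
#' native box. Every output record carries a truth label in
#' \code{{clean, duplicate, institution, out_of_range}} so that cleaning can
#' be validated against known ground truth.
#'
#' @param occurrences Occurrence data.frame (\code{species},
#'   \code{longitude}, \code{latitude}, \code{record_id}).
#' @param native_boxes Data.frame \code{species}, \code{lon_min},
#'   \code{lon_max}, \code{lat_min}, \code{lat_max}; must cover each
#'   species' clean points and be present for any species receiving
#'   out-of-range contaminants.
#' @param spec A \code{\link{contamination_spec}}.
#' @return Data.frame of all records with an added \code{label} column.
#' @export
inject_contaminants <- function(occurrences, native_boxes, spec) {
  stopifnot(inherits(spec, "contamination_spec"))
  occurrences$label <- "clean"
  out <- list(occurrences)
  species <- unique(occurrences$species)
  if (spec$n_out_of_range > 0) {
    missing_box <- setdiff(species, native_boxes$species)
    if (length(missing_box) > 0) {
      stop("native box missing for species receiving contaminants: ",
           paste(missing_box, collapse = ", "), call. = FALSE)
    }
  }
  for (sp in species) {
    sp_rows <- occurrences[occurrences$species == sp, , drop = FALSE]
    with_seed(derive_seed(spec$seed, sp), {
      if (spec$n_duplicates > 0) {
        pick <- sp_rows[sample.int(nrow(sp_rows), spec$n_duplicates, replace = TRUE), ]
        pick$record_id <- sprintf("%s_dup%03d", sp, seq_len(spec$n_duplicates))
        pick$label <- "duplicate"
        out[[length(out) + 1L]] <- pick
      }
      if (spec$n_institution > 0) {
        ip <- spec$institution_points[
          sample.int(nrow(spec$institution_points), spec$n_institution,
                     replace = TRUE), , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          species = sp, longitude = ip$longitude, latitude = ip$latitude,
          record_id = sprintf("%s_inst%03d", sp, seq_len(spec$n_institution)),
          label = "institution", stringsAsFactors = FALSE)
      }
      if (spec$n_out_of_range > 0) {
        box <- native_boxes[native_boxes$species == sp, , drop = FALSE][1, ]
        # Displace east of the box by 1-2 box widths (a disjoint region).
        bw <- max(box$lon_max - box$lon_min, 1)
        lon <- box$lon_max + stats::runif(spec$n_out_of_range, bw, 2 * bw)
        lat <- stats::runif(spec$n_out_of_range, box$lat_min, box$lat_max)
        out[[length(out) + 1L]] <- data.frame(
          species = sp, longitude = lon, latitude = lat,
          record_id = sprintf("%s_oor%03d", sp, seq_len(spec$n_out_of_range)),
          label = "out_of_range", stringsAsFactors = FALSE)
      }
    })
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$species, res$record_id), , drop = FALSE]
}

#' Axis-aligned native boxes covering each species' points
#'
#' Convenience for simulation studies: the tight bounding box of each
#' species' occurrences, optionally padded.
#'
#' @param occurrences Occurrence data.frame.
#' @param pad Padding in degrees added on every side.
#' @return Data.frame \code{species}, \code{lon_min}, \code{lon_max},
#'   \code{lat_min}, \code{lat_max}.
#' @export
native_boxes_from_occurrences <- function(occurrences, pad = 0.01) {
  sp <- split(occurrences, occurrences$species)
  out <- lapply(sp, function(d) {
    data.frame(species = d$species[1],
               lon_min = min(d$longitude) - pad, lon_max = max(d$longitude) + pad,
               lat_min = min(d$latitude) - pad, lat_max = max(d$latitude) + pad,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
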
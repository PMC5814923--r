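#' Load occurrence records from CSV
#'
#' Expects columns \code{species}, \code{longitude}, \code{latitude},
#' \code{record_id}. Rows with missing or out-of-bounds coordinates
#' (longitude outside [-180, 180], latitude outside [-90, 90]) or empty
#' species are rejected, with their file row numbers reported.
#'
#' @param path Path to a CSV file.
#' @return List with \code{records} (validated data.frame) and
#'   \code{rejected} (data.frame \code{row}, \code{reason}).
#' @export
load_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "longitude", "latitude", "record_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty occurrence file: ", path)
    return(list(records = df[required], rejected = data.frame(row = integer(0),
                                                              reason = character(0))))
  }
  df$species <- as.character(df$species)
  df$record_id <- as.character(df$record_id)
  lon_ok <- is.finite(df$longitude) & df$longitude >= -180 & df$longitude <= 180
  lat_ok <- is.finite(df$latitude) & df$latitude >= -90 & df$latitude <= 90
  sp_ok <- !is.na(df$species) & nzchar(df$species)
  bad <- !(lon_ok & lat_ok & sp_ok)
  reason <- character(sum(bad))
  reason[!sp_ok[bad]] <- "missing species"
  reason[!lat_ok[bad]] <- "invalid latitude"
  reason[!lon_ok[bad]] <- "invalid longitude"
  list(records = df[!bad, required, drop = FALSE],
       rejected = data.frame(row = which(bad), reason = reason,
                             stringsAsFactors = FALSE))
}

#' Clean occurrence records
#'
#' Applies, in a fixed order, the three quality-control filters used for
#' herbarium-derived presence data, then the minimum-sample-size rule:
#' \enumerate{
#'   \item exact duplicates within species (coordinates rounded to
#'     \code{duplicate_dp} decimal places), keeping the first record by
#'     \code{record_id} sort order;
#'   \item records within \code{institution_tolerance_deg} (Euclidean
#'     degrees) of any institution decoy coordinate;
#'   \item records outside the species' native box (species without a box
#'     skip this rule, with a warning);
#'   \item species with fewer than \code{min_points} retained records are
#'     excluded entirely.
#' }
#' The report satisfies, per species,
#' \code{n_input = n_retained + n_removed_duplicate + n_removed_institution
#' + n_removed_outside}.
#'
#' @param records Occurrence data.frame (\code{species}, \code{longitude},
#'   \code{latitude}, \code{record_id}).
#' @param native_regions Optional data.frame \code{species}, \code{lon_min},
#'   \code{lon_max}, \code{lat_min}, \code{lat_max}.
#' @param institution_points Optional two-column (lon, lat) data.frame or
#'   matrix of institution coordinates.
#' @param min_points Minimum retained records for a species to be kept
#'   (default 3, the standard inclusion rule; must be >= 1).
#' @param institution_tolerance_deg Match radius in degrees for rule 2
#'   (default 0.001, about 100 m, absorbing coordinate rounding).
#' @param duplicate_dp Decimal places for the duplicate-coordinate rounding
#'   (default 4, about 11 m).
#' @return List with \code{records} (retained, sorted by species then
#'   record_id), \code{report} (per-species count data.frame) and
#'   \code{excluded_species} (character vector).
#' @export
clean_occurrences <- function(records, native_regions = NULL,
                              institution_points = NULL, min_points = 3,
                              institution_tolerance_deg = 0.001,
                              duplicate_dp = 4) {
  if (min_points < 1) stop("min_points must be >= 1", call. = FALSE)
  if (!is.null(institution_points)) {
    institution_points <- as.data.frame(institution_points)
    names(institution_points)[1:2] <- c("longitude", "latitude")
  }
  records <- records[order(records$species, records$record_id), , drop = FALSE]
  species <- unique(records$species)
  no_box <- if (is.null(native_regions)) species else
    setdiff(species, native_regions$species)
  if (length(no_box) > 0 && !is.null(native_regions)) {
    warning("no native region for: ", paste(no_box, collapse = ", "),
            "; out-of-range rule skipped for these species")
  }
  rep_rows <- list()
  keep <- list()
  for (sp in species) {
    d <- records[records$species == sp, , drop = FALSE]
    n_input <- nrow(d)
    # (1) duplicates: same rounded coordinates; first by record_id kept
    key <- paste(round(d$longitude, duplicate_dp),
                 round(d$latitude, duplicate_dp))
    dup <- duplicated(key)
    n_dup <- sum(dup)
    d <- d[!dup, , drop = FALSE]
    # (2) institution coordinates
    n_inst <- 0L
    if (!is.null(institution_points) && nrow(institution_points) > 0 && nrow(d) > 0) {
      dmin <- vapply(seq_len(nrow(d)), function(i) {
        min(sqrt((d$longitude[i] - institution_points$longitude)^2 +
                   (d$latitude[i] - institution_points$latitude)^2))
      }, numeric(1))
      at_inst <- dmin <= institution_tolerance_deg
      n_inst <- sum(at_inst)
      d <- d[!at_inst, , drop = FALSE]
    }
    # (3) outside native region
    n_out <- 0L
    if (!(sp %in% no_box) && nrow(d) > 0) {
      box <- native_regions[native_regions$species == sp, , drop = FALSE][1, ]
      inside <- d$longitude >= box$lon_min & d$longitude <= box$lon_max &
        d$latitude >= box$lat_min & d$latitude <= box$lat_max
      n_out <- sum(!inside)
      d <- d[inside, , drop = FALSE]
    }
    rep_rows[[sp]] <- data.frame(
      species = sp, n_input = n_input, n_removed_duplicate = n_dup,
      n_removed_institution = n_inst, n_removed_outside = n_out,
      n_retained = nrow(d), stringsAsFactors = FALSE)
    keep[[sp]] <- d
  }
  report <- do.call(rbind, c(rep_rows, list(make.row.names = FALSE)))
  excluded <- report$species[report$n_retained < min_points]
  kept_species <- setdiff(species, excluded)
  retained <- if (length(kept_species) == 0) {
    records[0, , drop = FALSE]
  } else {
    do.call(rbind, c(keep[kept_species], list(make.row.names = FALSE)))
  }
  list(records = retained, report = report,
       excluded_species = excluded)
}
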
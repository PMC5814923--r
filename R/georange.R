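#' Convex hull of presence points in geographic coordinates
#'
#' Hull computed in the lon/lat plane (the convention of desktop-GIS convex
#' hull tools), returned as a counter-clockwise closed ring with collinear
#' boundary points removed. Fewer than three unique points, or a fully
#' collinear set, yields a degenerate (empty-ring) result.
#'
#' @param longitude,latitude Numeric vectors of WGS84 coordinates.
#' @return List with \code{ring} (closed CCW (lon, lat) matrix, first row
#'   repeated last; 0 rows when degenerate), \code{degenerate} (logical) and
#'   \code{n_points} (input point count).
#' @export
convex_hull <- function(longitude, latitude) {
  stopifnot(length(longitude) == length(latitude), length(longitude) >= 1)
  if (any(!is.finite(longitude)) || any(!is.finite(latitude)) ||
      any(abs(longitude) > 180) || any(abs(latitude) > 90)) {
    stop("invalid coordinates", call. = FALSE)
  }
  pts <- unique(cbind(lon = longitude, lat = latitude))
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lon", "lat")))
  if (nrow(pts) < 3) {
    return(list(ring = empty, degenerate = TRUE, n_points = length(longitude)))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise vertex order
  ring <- pts[rev(h), , drop = FALSE]        # counter-clockwise
  if (nrow(ring) < 3 || shoelace_area(ring) == 0) {
    return(list(ring = empty, degenerate = TRUE, n_points = length(longitude)))
  }
  list(ring = rbind(ring, ring[1, , drop = FALSE]), degenerate = FALSE,
       n_points = length(longitude))
}

#' Geodesic polygon area on the WGS84 ellipsoid
#'
#' Area of a convex-hull ring in square kilometres, computed on the WGS84
#' ellipsoid. Degenerate hulls have area 0. Rings spanning 180 degrees or
#' more of longitude (antimeridian wrap) are not supported and raise an
#' error.
#'
#' @param hull Result of \code{\link{convex_hull}}, or a closed (lon, lat)
#'   ring matrix.
#' @return Area in km^2 (nonnegative).
#' @export
ellipsoidal_area <- function(hull) {
  ring <- if (is.list(hull) && !is.null(hull$ring)) hull$ring else hull
  if (is.null(nrow(ring)) || nrow(ring) < 4) return(0)
  if (diff(range(ring[, 1])) >= 180) {
    stop("hull spans >= 180 degrees of longitude (antimeridian wrap unsupported)",
         call. = FALSE)
  }
  open_ring <- ring[-nrow(ring), , drop = FALSE]
  abs(geosphere::areaPolygon(open_ring)) / 1e6
}

#' Species geographic range sizes (extent of occurrence)
#'
#' Fits the convex hull of each species' presence points and measures its
#' geodesic area on the WGS84 ellipsoid, the extent-of-occurrence range-size
#' estimate in km^2. Species with degenerate hulls (all points collinear or
#' fewer than three unique locations) get area 0 and a degenerate flag.
#'
#' @param records Occurrence data.frame (\code{species}, \code{longitude},
#'   \code{latitude}).
#' @return Data.frame \code{species}, \code{n_points}, \code{area_km2},
#'   \code{degenerate}.
#' @export
species_georanges <- function(records) {
  sp <- split(records, records$species)
  rows <- lapply(sp, function(d) {
    h <- convex_hull(d$longitude, d$latitude)
    data.frame(species = d$species[1], n_points = nrow(d),
               area_km2 = ellipsoidal_area(h), degenerate = h$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
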
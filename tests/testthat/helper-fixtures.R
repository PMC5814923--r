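# Shared fixtures and independent oracles for the test suite.

# A tiny fully hand-specified 3x3 stack: origin upper-left (0, 3), 1-degree
# cells, north-up. AI carries one nodata cell at row 1, col 1.
tiny_stack <- function() {
  m <- function(v) matrix(v, 3, 3, byrow = TRUE)
  layers <- list(
    MAP    = m(c(100, 200, 300, 400, 500, 600, 700, 800, 900)),
    P_dry  = m(c(1, 2, 3, 4, 5, 6, 7, 8, 9)),
    P_seas = m(c(10, 20, 30, 40, 50, 60, 70, 80, 90)),
    AET    = m(c(50, 60, 70, 80, 90, 100, 110, 120, 130)),
    PET    = m(c(100, 120, 140, 160, 180, 200, 220, 240, 260)),
    AI     = m(c(NA, 16667, 21429, 25000, 27778, 30000, 31818, 33333, 34615))
  )
  climate_stack(layers, origin_lon = 0, origin_lat = 3, cell_size = 1)
}

# Quick default landscape for simulation tests.
quick_landscape <- function(seed = 42L, n = 80L) {
  generate_climate_stack(landscape_spec(n_cols = n, n_rows = n, seed = seed))
}

# Summary-shaped table built directly from per-variable value matrices
# (rows = species), bypassing extraction. Used by PCA/overlap/regression
# tests that operate on species summaries.
summaries_from_values <- function(value_list, species = NULL) {
  n <- nrow(value_list[[1]])
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n))
  out <- data.frame(species = species, n_points_used = rep(3L, n),
                    stringsAsFactors = FALSE)
  for (v in names(value_list)) {
    x <- value_list[[v]]
    out[[paste0(v, "_mean")]] <- rowMeans(x)
    out[[paste0(v, "_min")]] <- apply(x, 1, min)
    out[[paste0(v, "_max")]] <- apply(x, 1, max)
    out[[paste0(v, "_range")]] <- apply(x, 1, max) - apply(x, 1, min)
  }
  out
}

# Summary table whose five indicator sets are independent random draws.
random_summaries <- function(n, seed) {
  withr_seed <- function(code) code  # no-op marker; seed set by caller
  set.seed(seed)
  vals <- lapply(hydro_indicators(), function(v) {
    center <- runif(n, 50, 150)
    half <- runif(n, 1, 40)
    cbind(center - half, center, center + half)
  })
  names(vals) <- hydro_indicators()
  summaries_from_values(vals)
}

# Oracle: mean/sd of pairwise interval overlaps by an explicit double loop.
bf_overlap_stats <- function(lo, hi) {
  n <- length(lo)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, max(0, min(hi[i], hi[j]) - max(lo[i], lo[j])))
  }
  list(mean = mean(vals), sd = sd(vals), mean_range = mean(hi - lo))
}

# Oracle: convex-hull area via O(n^3) brute force. An edge (i, j) is a hull
# edge iff every other point lies on one side of the line through i and j;
# hull vertices are endpoints of hull edges, ordered by angle about their
# centroid, then shoelace.
bf_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xy[j, ] - xy[i, ]
    cr <- (xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1]
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) on_hull[c(i, j)] <- TRUE
  }
  v <- xy[on_hull, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  k <- c(2:nrow(v), 1)
  abs(sum(x * y[k] - x[k] * y)) / 2
}

# Oracle: spherical-excess polygon area (l'Huilier) on the authalic sphere,
# in km^2, for a counter-clockwise (lon, lat) ring (open, >= 3 vertices).
lhuilier_area <- function(ring, R = 6371.0072) {
  tocart <- function(lon, lat) {
    lam <- lon * pi / 180; phi <- lat * pi / 180
    c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  tri <- function(p1, p2, p3) {
    ang <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v))))
    a <- ang(p2, p3); b <- ang(p1, p3); cc <- ang(p1, p2)
    s <- (a + b + cc) / 2
    t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - cc) / 2)
    4 * atan(sqrt(max(0, t)))
  }
  p <- lapply(seq_len(nrow(ring)), function(i) tocart(ring[i, 1], ring[i, 2]))
  E <- 0
  for (i in 2:(length(p) - 1)) E <- E + tri(p[[1]], p[[i]], p[[i + 1]])
  R^2 * E
}

# A small contaminated synthetic cohort with truth labels, shared by
# cleaning and pipeline tests.
contaminated_cohort <- function(seed = 11L) {
  st <- quick_landscape(seed = seed)
  rng <- range(st$layers$MAP)
  niches <- lapply(1:6, function(i) {
    niche_spec(sprintf("sp%02d", i),
               optima = c(MAP = rng[1] + i / 7 * diff(rng)),
               breadth_sigma = c(MAP = 0.1 * diff(rng)),
               n_points = 12)
  })
  g <- generate_species_occurrences(st, niches, seed = seed)
  boxes <- native_boxes_from_occurrences(g$occurrences)
  inst <- data.frame(longitude = c(-74.2, -73.1), latitude = c(-1.1, -2.3))
  spec <- contamination_spec(n_duplicates = 3, institution_points = inst,
                             n_institution = 2, n_out_of_range = 2, seed = seed)
  list(stack = st, truth = g$truth, boxes = boxes, institutions = inst,
       contaminated = inject_contaminants(g$occurrences, boxes, spec),
       spec = spec)
}
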
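#' Specification of one synthetic climate field
#'
#' Describes how a single bioclimatic layer is generated: a spatially
#' autocorrelated noise field affinely rescaled to
#' \code{[base_level - amplitude, base_level + amplitude]} and clamped to
#' \code{[clamp_min, clamp_max]}.
#'
#' @param base_level Central value of the field, in the variable's units.
#' @param amplitude Half-width of the target value interval; 0 yields a
#'   constant field at \code{base_level}.
#' @param smoothing_length_cells Standard deviation (in cells) of the
#'   Gaussian smoothing kernel controlling spatial autocorrelation.
#' @param clamp_min,clamp_max Hard bounds applied after rescaling.
#' @return A \code{field_spec} list.
#' @export
field_spec <- function(base_level, amplitude, smoothing_length_cells,
                       clamp_min = 0, clamp_max = Inf) {
  check_that(is.numeric(base_level) && length(base_level) == 1L, "base_level", "must be a single number")
  check_that(is.numeric(amplitude) && amplitude >= 0, "amplitude", "must be >= 0")
  check_that(is.numeric(smoothing_length_cells) && smoothing_length_cells > 0,
             "smoothing_length_cells", "must be > 0")
  check_that(clamp_min >= 0, "clamp_min", "must be >= 0")
  check_that(clamp_min <= clamp_max, "clamp_min", "must be <= clamp_max")
  structure(list(base_level = base_level, amplitude = amplitude,
                 smoothing_length_cells = smoothing_length_cells,
                 clamp_min = clamp_min, clamp_max = clamp_max),
            class = "field_spec")
}

#' Specification of a synthetic climate landscape
#'
#' Defines the grid geometry and the per-variable field specifications for a
#' seeded synthetic landscape. Variables fall into two latent blocks — an
#' overall-moisture block (MAP, AET, PET; PET loading negatively, so wet
#' regions have low evaporative demand and the derived aridity index tracks
#' MAP closely) and a seasonality block (P_seas, with P_dry loading
#' negatively). \code{cross_block_correlation} sets the target correlation
#' between the two latent fields.
#'
#' @param n_cols,n_rows Grid size in cells (>= 2 each).
#' @param origin_lon,origin_lat Upper-left corner of the grid, degrees WGS84.
#' @param cell_size Cell size in degrees (> 0); the grid is north-up with
#'   row 1 starting at \code{origin_lat}.
#' @param fields Named list of \code{\link{field_spec}} for
#'   MAP, P_dry, P_seas, AET, PET. Defaults emulate a Neotropical
#'   precipitation/evapotranspiration regime.
#' @param cross_block_correlation Target correlation in [-1, 1] between the
#'   moisture and seasonality latent fields (default 0).
#' @param block_weight Share (0..1) of each variable's latent field taken
#'   from its block latent, the rest being variable-specific noise.
#' @param seed Integer seed; identical specs produce bit-identical stacks.
#' @return A \code{landscape_spec} list.
#' @export
landscape_spec <- function(n_cols = 120, n_rows = 120,
                           origin_lon = -75, origin_lat = 0,
                           cell_size = 0.05,
                           fields = default_field_specs(),
                           cross_block_correlation = 0,
                           block_weight = 0.7,
                           seed = 1L) {
  check_that(n_cols >= 2 && n_rows >= 2, "n_cols/n_rows", "must be >= 2")
  check_that(cell_size > 0, "cell_size", "must be > 0")
  check_that(abs(cross_block_correlation) <= 1, "cross_block_correlation", "must lie in [-1, 1]")
  check_that(block_weight >= 0 && block_weight <= 1, "block_weight", "must lie in [0, 1]")
  needed <- setdiff(STACK_LAYERS, "AI")
  check_that(all(needed %in% names(fields)), "fields",
             paste("must provide specs for", paste(needed, collapse = ", ")))
  for (v in needed) {
    check_that(inherits(fields[[v]], "field_spec"), paste0("fields$", v),
               "must be a field_spec")
  }
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, fields = fields[needed],
                 cross_block_correlation = cross_block_correlation,
                 block_weight = block_weight, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Default per-variable field specifications
#'
#' Magnitudes follow the conventions of global precipitation /
#' evapotranspiration layers: MAP and AET/PET in mm per year, P_dry in mm per
#' month, P_seas as a coefficient-of-variation percentage. PET is clamped
#' away from zero so the aridity-index ratio is defined everywhere by
#' default.
#'
#' @return Named list of \code{\link{field_spec}} objects.
#' @export
default_field_specs <- function() {
  list(
    MAP    = field_spec(1800, 1600, 8, clamp_min = 0,   clamp_max = 8000),
    P_dry  = field_spec(60,   60,   8, clamp_min = 0,   clamp_max = 500),
    P_seas = field_spec(60,   45,   8, clamp_min = 0,   clamp_max = 180),
    AET    = field_spec(1000, 500,  8, clamp_min = 0,   clamp_max = 2200),
    PET    = field_spec(1500, 500,  8, clamp_min = 300, clamp_max = 2600)
  )
}

# Block membership and sign of each raw variable's loading on its block
# latent field.
BLOCK_OF <- c(MAP = "moisture", AET = "moisture", PET = "moisture",
              P_seas = "seasonality", P_dry = "seasonality")
BLOCK_SIGN <- c(MAP = 1, AET = 1, PET = -1, P_seas = 1, P_dry = -1)

# Smooth a matrix with a separable Gaussian kernel of sd `len` cells.
# Row/column kernel matrices are renormalized so edges are unbiased.
gaussian_smooth <- function(m, len) {
  kern_mat <- function(n) {
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = len)
    k / rowSums(k)
  }
  kern_mat(nrow(m)) %*% m %*% t(kern_mat(ncol(m)))
}

# A standardized (zero-mean, unit-sd) smoothed uniform-noise field.
smooth_noise_field <- function(n_rows, n_cols, len) {
  f <- gaussian_smooth(matrix(stats::runif(n_rows * n_cols), n_rows, n_cols), len)
  s <- stats::sd(f)
  if (s == 0) return(matrix(0, n_rows, n_cols))
  (f - mean(f)) / s
}

#' Generate a synthetic bioclimatic raster stack
#'
#' Produces six co-registered layers: MAP, P_dry, P_seas, AET and PET as
#' smoothed, clamped seeded noise fields with the two-block latent
#' correlation structure of the spec, and AI derived cell-wise as
#' \code{round(10000 * MAP / PET)} (the CGIAR scaled-integer convention),
#' with nodata (NA) where PET is 0.
#'
#' @param spec A \code{\link{landscape_spec}}.
#' @return A \code{climate_stack}: list of layer matrices plus grid geometry.
#' @export
generate_climate_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  layers <- with_seed(spec$seed, {
    rho <- spec$cross_block_correlation
    w <- spec$block_weight
    # Shared smoothing length for the block latents: mean of the variable
    # smoothing lengths (latents only carry the cross-variable structure).
    lens <- vapply(spec$fields, function(f) f$smoothing_length_cells, numeric(1))
    latent_len <- mean(lens)
    moist <- smooth_noise_field(spec$n_rows, spec$n_cols, latent_len)
    seas0 <- smooth_noise_field(spec$n_rows, spec$n_cols, latent_len)
    seas <- rho * moist + sqrt(max(0, 1 - rho^2)) * seas0
    out <- list()
    for (v in names(spec$fields)) {
      fs <- spec$fields[[v]]
      block <- if (BLOCK_OF[[v]] == "moisture") moist else seas
      own <- smooth_noise_field(spec$n_rows, spec$n_cols, fs$smoothing_length_cells)
      z <- BLOCK_SIGN[[v]] * w * block + sqrt(max(0, 1 - w^2)) * own
      if (fs$amplitude == 0 || diff(range(z)) == 0) {
        f <- matrix(fs$base_level, spec$n_rows, spec$n_cols)
      } else {
        f <- fs$base_level - fs$amplitude +
          (z - min(z)) / diff(range(z)) * (2 * fs$amplitude)
      }
      out[[v]] <- pmin(pmax(f, fs$clamp_min), fs$clamp_max)
    }
    out
  })
  ai <- round(10000 * layers$MAP / layers$PET)
  ai[layers$PET == 0] <- NA_real_
  layers$AI <- ai
  climate_stack(layers,
                origin_lon = spec$origin_lon, origin_lat = spec$origin_lat,
                cell_size = spec$cell_size)
}

#' Construct a climate stack from layer matrices
#'
#' @param layers Named list of numeric matrices (MAP, P_dry, P_seas, AET,
#'   PET, AI) sharing one grid; NA encodes nodata.
#' @param origin_lon,origin_lat Upper-left grid corner, degrees.
#' @param cell_size Cell size in degrees.
#' @return A \code{climate_stack} object.
#' @export
climate_stack <- function(layers, origin_lon, origin_lat, cell_size) {
  check_that(all(STACK_LAYERS %in% names(layers)), "layers",
             paste("must contain", paste(STACK_LAYERS, collapse = ", ")))
  dims <- unique(lapply(layers[STACK_LAYERS], dim))
  check_that(length(dims) == 1L, "layers", "must share identical grid dimensions")
  check_that(cell_size > 0, "cell_size", "must be > 0")
  check_that(all(layers$AI >= 0, na.rm = TRUE), "AI", "must be nonnegative")
  structure(list(layers = layers[STACK_LAYERS],
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size,
                 n_rows = nrow(layers$MAP), n_cols = ncol(layers$MAP)),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d x %d cells, %.4g deg, origin (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  for (v in names(x$layers)) {
    rng <- range(x$layers[[v]], na.rm = TRUE)
    cat(sprintf("  %-7s [%.6g, %.6g], %d nodata cells\n", v, rng[1], rng[2],
                sum(is.na(x$layers[[v]]))))
  }
  invisible(x)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format; rows written north to
#' south, NA cells written as the nodata sentinel.
#'
#' @param m Numeric matrix (row 1 = northernmost row).
#' @param path Output file path.
#' @param origin_lon,origin_lat Upper-left grid corner, degrees.
#' @param cell_size Cell size in degrees.
#' @param nodata Sentinel value for NA cells.
#' @export
write_ascii_grid <- function(m, path, origin_lon, origin_lat, cell_size,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", origin_lon),
               sprintf("yllcorner %.10g", origin_lat - nrow(m) * cell_size),
               sprintf("cellsize %.10g", cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by \code{\link{write_ascii_grid}} or any
#'   conforming ESRI ASCII grid.
#' @return List with \code{matrix}, \code{origin_lon}, \code{origin_lat}
#'   (upper-left corner) and \code{cell_size}; nodata cells are NA.
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6L)
  hdr <- list()
  for (l in hdr_lines) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(matrix = m,
       origin_lon = hdr$xllcorner,
       origin_lat = hdr$yllcorner + hdr$nrows * hdr$cellsize,
       cell_size = hdr$cellsize)
}

#' Write all layers of a climate stack as ASCII grids
#'
#' One \code{<variable>.asc} file per layer in \code{dir}.
#'
#' @param stack A \code{climate_stack}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_climate_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "climate_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (v in names(stack$layers)) {
    p <- file.path(dir, paste0(v, ".asc"))
    write_ascii_grid(stack$layers[[v]], p, stack$origin_lon, stack$origin_lat,
                     stack$cell_size)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a climate stack from a directory of ASCII grids
#'
#' @param dir Directory holding \code{MAP.asc}, \code{P_dry.asc},
#'   \code{P_seas.asc}, \code{AET.asc}, \code{PET.asc}, \code{AI.asc}.
#' @return A \code{climate_stack}.
#' @export
read_climate_stack <- function(dir) {
  grids <- lapply(STACK_LAYERS, function(v) {
    p <- file.path(dir, paste0(v, ".asc"))
    if (!file.exists(p)) stop("missing layer file: ", p, call. = FALSE)
    read_ascii_grid(p)
  })
  names(grids) <- STACK_LAYERS
  g1 <- grids[[1]]
  climate_stack(lapply(grids, `[[`, "matrix"),
                origin_lon = g1$origin_lon, origin_lat = g1$origin_lat,
                cell_size = g1$cell_size)
}
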
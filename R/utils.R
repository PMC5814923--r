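#' @keywords internal
"_PACKAGE"

# The five univariate hydrological habitat indicators used throughout.
# AET_PET is the per-point ratio of actual to potential evapotranspiration;
# AI is the CGIAR-style scaled aridity index (10^4 * MAP / PET).
HYDRO_INDICATORS <- c("MAP", "AI", "AET_PET", "P_dry", "P_seas")

# Raw raster layers a climate stack must carry (AI is derived from MAP/PET).
STACK_LAYERS <- c("MAP", "P_dry", "P_seas", "AET", "PET", "AI")

#' Indicator variable names
#'
#' Returns the names of the five univariate hydrological habitat indicators:
#' mean annual precipitation (MAP, mm), aridity index (AI, dimensionless,
#' stored as the 10^4-scaled integer convention), the ratio of actual to
#' potential evapotranspiration (AET_PET), precipitation of the driest month
#' (P_dry, mm) and precipitation seasonality (P_seas, %).
#'
#' @return Character vector of length 5.
#' @export
hydro_indicators <- function() HYDRO_INDICATORS

# Stable 32-bit string hash (djb2 variant), used to derive per-species
# RNG sub-streams so generated point sets do not depend on insertion order.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (code in utf8ToInt(x)) {
    h <- (h * 33 + code) %% 2147483647
  }
  as.integer(h)
}

# Derive a child seed from a parent seed and a label; keeps everything
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  as.integer((as.double(seed) + as.double(stable_hash(label))) %% 2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
# Makes every generator a pure function of its spec (including seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validation helper: stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  invisible(TRUE)
}
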
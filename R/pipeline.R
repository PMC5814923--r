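#' Build a pipeline configuration
#'
#' Collects inputs (as file paths or in-memory objects) and the analysis
#' parameters for an end-to-end run. Defaults are the standard settings used
#' throughout the package: minimum three presence points per species,
#' duplicate coordinates rounded to 4 decimal places, 0.001 degree
#' institution match radius, log10(x + 1) transforms, overlap on AI and
#' P_seas, genus hulls from three species, collinearity flag at r2 = 0.70.
#'
#' @param occurrences Occurrence CSV path or data.frame.
#' @param stack Climate stack directory (ASCII grids) or
#'   \code{climate_stack} object.
#' @param native_regions Optional native-box CSV path or data.frame.
#' @param institutions Optional institution-coordinate CSV path or
#'   data.frame (columns including \code{longitude}, \code{latitude}).
#' @param groups Genus/group assignment CSV path or data.frame
#'   (\code{species}, \code{group}).
#' @param functional_types Optional CSV path or data.frame (\code{species},
#'   \code{functional_type}).
#' @param richness Optional CSV path or data.frame (\code{group},
#'   \code{richness}).
#' @param out_dir Output directory for tables and the manifest.
#' @param min_points,duplicate_dp,institution_tolerance_deg,log_offset
#'   Cleaning and transform parameters (see the stage functions).
#' @param overlap_variables Indicators for the overlap table.
#' @param hull_min_species Minimum species per group for PC hulls.
#' @param collinearity_threshold Flagging threshold for the variable screen.
#' @param seed Master seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed governs any upstream simulation).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(occurrences, stack, native_regions = NULL,
                            institutions = NULL, groups = NULL,
                            functional_types = NULL, richness = NULL,
                            out_dir = "results/run",
                            min_points = 3, duplicate_dp = 4,
                            institution_tolerance_deg = 0.001,
                            log_offset = 1,
                            overlap_variables = c("AI", "P_seas"),
                            hull_min_species = 3,
                            collinearity_threshold = 0.70,
                            seed = 1L) {
  check_that(min_points >= 1, "min_points", "must be >= 1")
  check_that(log_offset > 0, "log_offset", "must be > 0")
  structure(list(occurrences = occurrences, stack = stack,
                 native_regions = native_regions, institutions = institutions,
                 groups = groups, functional_types = functional_types,
                 richness = richness, out_dir = out_dir,
                 min_points = min_points, duplicate_dp = duplicate_dp,
                 institution_tolerance_deg = institution_tolerance_deg,
                 log_offset = log_offset,
                 overlap_variables = overlap_variables,
                 hull_min_species = hull_min_species,
                 collinearity_threshold = collinearity_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Resolve an input that may be a path or an in-memory object; records the
# checksum of file inputs in the manifest.
resolve_table <- function(x, manifest, name) {
  if (is.null(x) || is.data.frame(x)) return(list(value = x, manifest = manifest))
  stopifnot(is.character(x))
  manifest$input_checksums[[name]] <- unname(tools::md5sum(x))
  list(value = utils::read.csv(x, stringsAsFactors = FALSE), manifest = manifest)
}

#' Run the full habitat-occupancy pipeline
#'
#' Executes clean -> extract -> summarize -> PCA (position and range) ->
#' overlap -> georange -> hypothesis report, writing every stage's table as
#' CSV plus a JSON manifest (parameters, seed, input checksums, per-stage
#' record counts) to the configured output directory. Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("hydroniche")),
                   seed = config$seed,
                   parameters = config[c("min_points", "duplicate_dp",
                                         "institution_tolerance_deg", "log_offset",
                                         "overlap_variables", "hull_min_species",
                                         "collinearity_threshold")],
                   input_checksums = list(), counts = list())

  # -- inputs
  if (is.character(config$occurrences)) {
    manifest$input_checksums$occurrences <- unname(tools::md5sum(config$occurrences))
    loaded <- load_occurrences(config$occurrences)
    occ <- loaded$records
    manifest$counts$rejected_rows <- nrow(loaded$rejected)
  } else {
    occ <- config$occurrences
  }
  stack <- if (is.character(config$stack)) read_climate_stack(config$stack) else config$stack
  r <- resolve_table(config$native_regions, manifest, "native_regions")
  native_regions <- r$value; manifest <- r$manifest
  r <- resolve_table(config$institutions, manifest, "institutions")
  institutions <- r$value; manifest <- r$manifest
  r <- resolve_table(config$groups, manifest, "groups")
  groups <- r$value; manifest <- r$manifest
  r <- resolve_table(config$functional_types, manifest, "functional_types")
  functional_types <- r$value; manifest <- r$manifest
  r <- resolve_table(config$richness, manifest, "richness")
  richness <- r$value; manifest <- r$manifest

  out <- function(name, df) {
    utils::write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  # -- clean
  cleaned <- clean_occurrences(occ, native_regions, institutions,
                               min_points = config$min_points,
                               institution_tolerance_deg = config$institution_tolerance_deg,
                               duplicate_dp = config$duplicate_dp)
  manifest$counts$input_records <- nrow(occ)
  manifest$counts$retained_records <- nrow(cleaned$records)
  manifest$counts$excluded_species <- cleaned$excluded_species
  out("cleaning_report", cleaned$report)
  out("cleaned_occurrences", cleaned$records)

  # -- extract + summarize
  values <- extract_values(stack, cleaned$records)
  manifest$counts$points_dropped_outside <- attr(values, "drop_log")$n_outside
  manifest$counts$points_dropped_nodata <- attr(values, "drop_log")$n_nodata
  summaries <- summarize_species(values, min_points = config$min_points)
  manifest$counts$species_summarized <- nrow(summaries)
  out("point_values", values)
  out("species_summaries", summaries)

  screen <- variable_collinearity_screen(summaries,
                                         threshold = config$collinearity_threshold)
  out("collinearity_flagged", screen$flagged)
  utils::write.csv(screen$r2, file.path(config$out_dir, "collinearity_r2.csv"))

  # -- habitat spaces
  spaces <- list(position = fit_habitat_space(summaries, "position",
                                              log_offset = config$log_offset),
                 range = fit_habitat_space(summaries, "range",
                                           log_offset = config$log_offset))
  for (k in names(spaces)) {
    utils::write.csv(spaces[[k]]$loadings,
                     file.path(config$out_dir, paste0("loadings_", k, ".csv")))
    utils::write.csv(spaces[[k]]$scores,
                     file.path(config$out_dir, paste0("scores_", k, ".csv")))
    out(paste0("variance_", k),
        data.frame(component = seq_along(spaces[[k]]$variance_explained),
                   fraction = spaces[[k]]$variance_explained))
  }

  # -- overlap, georange, hypotheses
  overlap <- if (!is.null(groups)) {
    overlap_table(summaries, groups, variables = config$overlap_variables)
  }
  if (!is.null(overlap)) out("overlap_table", overlap)

  georanges <- species_georanges(cleaned$records[
    cleaned$records$species %in% summaries$species, , drop = FALSE])
  out("georanges", georanges)

  report <- NULL
  if (!is.null(groups) && !is.null(functional_types) && !is.null(richness)) {
    report <- run_hypothesis_battery(summaries, georanges, groups,
                                     functional_types, richness,
                                     spaces = spaces,
                                     min_species = config$hull_min_species)
    out("h_position_vs_range", report$position_vs_range)
    out("h_georange_vs_habitat_range", report$georange_vs_habitat_range)
    out("h_richness_diversity", report$richness_diversity)
    out("h_sensitivity", report$sensitivity)
    out("genus_hulls", report$hulls)
    out("h_anova", data.frame(F = report$anova$F, p = report$anova$p))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cleaned = cleaned, values = values, summaries = summaries,
                 screen = screen, spaces = spaces, overlap = overlap,
                 georanges = georanges, report = report, manifest = manifest))
}
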
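#' Read a cohort configuration from JSON
#'
#' Parses a JSON run configuration into a [cohort_config()]. The file
#' carries the study layout (groups, timepoints, stage table, noise,
#' mortality, assays) plus the phantom geometry and the seed; anything
#' omitted falls back to the package defaults. A demo configuration
#' ships with the package:
#' `system.file("extdata", "demo_cohort.json", package = "fibrodens")`.
#'
#' @param path JSON file path.
#' @param rng_seed optional seed overriding the file's.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path, rng_seed = NULL) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- as.data.frame(cfg$groups, stringsAsFactors = FALSE)
  if (!is.null(groups$matched_vehicle))
    groups$matched_vehicle[groups$matched_vehicle == ""] <- NA
  stage_table <- as.data.frame(cfg$stage_table, stringsAsFactors = FALSE)
  assays <- if (is.null(cfg$assays)) list() else
    lapply(seq_along(cfg$assays$assay), function(i)
      list(assay = cfg$assays$assay[[i]],
           days = unlist(cfg$assays$days[[i]]),
           mean_by_day = unlist(cfg$assays$mean_by_day[[i]]),
           sd = cfg$assays$sd[[i]],
           n_replicates = as.integer(cfg$assays$n_replicates[[i]])))
  ph <- cfg$phantom
  phantom <- phantom_config(
    grid_shape = if (is.null(ph$grid_shape)) c(128L, 128L, 96L)
                 else unlist(ph$grid_shape),
    spacing_mm = if (is.null(ph$spacing_mm)) c(0.25, 0.25, 0.25)
                 else unlist(ph$spacing_mm),
    irradiated_side = if (is.null(ph$irradiated_side)) "right"
                      else ph$irradiated_side)
  cohort_config(
    groups = groups,
    timepoints = unlist(cfg$timepoints),
    stage_table = stage_table,
    histology_noise_sd = cfg$histology_noise_sd %||% 0.5,
    mortality_prob = unlist(cfg$mortality_prob),
    assays = assays,
    phantom = phantom,
    n_patch_seeds = as.integer(cfg$n_patch_seeds %||% 5L),
    rng_seed = as.integer(rng_seed %||% cfg$rng_seed %||% 1L))
}
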
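#' Cohort configuration for the synthetic study
#'
#' Describes a full preclinical study layout: treatment arms with their
#' matched vehicle controls, sacrifice timepoints, the consolidation
#' fraction each group reaches at each week, histology grading noise,
#' per-group mortality, and the assay timecourses. The default
#' configuration mirrors a hemithoracic-irradiation drug study: two drug
#' arms and two matched vehicle arms of n = 10, a 20-week endpoint,
#' vehicles progressing to near-total consolidation, one effective drug
#' (70% attenuation), one marginal drug with 50% mortality.
#'
#' @param groups data.frame with columns `group`, `treatment`,
#'   `matched_vehicle` (NA/"" for vehicle arms) and `n` (>= 1).
#' @param timepoints weeks at which animals are scanned/sacrificed.
#' @param stage_table data.frame `group, week, consolidation_fraction`
#'   covering every group x timepoint combination.
#' @param histology_noise_sd SD of the Gaussian grading noise added to the
#'   severity link `grade = clamp(round(4 f + noise), 0, 4)`.
#' @param mortality_prob named per-study death probability per group.
#' @param assays list of assay descriptors: each a list with `assay`,
#'   `days`, `mean_by_day` (same length as `days`), `sd`, `n_replicates`.
#' @param phantom base [phantom_config()] (grid, spacing, mixture, side)
#'   shared by all animals; its stage and seed are overridden per animal.
#' @param n_patch_seeds region-growing seeds per phantom.
#' @param rng_seed integer seed for the whole cohort.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(groups, timepoints, stage_table,
                          histology_noise_sd = 0.5,
                          mortality_prob = NULL,
                          assays = list(),
                          phantom = phantom_config(),
                          n_patch_seeds = 5L,
                          rng_seed = 1L) {
  need <- c("group", "treatment", "matched_vehicle", "n")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop("groups table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(groups$n < 1)) stop("every group needs n >= 1", call. = FALSE)
  veh <- groups$matched_vehicle
  has_vehicle <- !is.na(veh) & veh != ""
  if (any(has_vehicle & !(veh %in% groups$group)))
    stop("every drug group must name an existing vehicle group", call. = FALSE)
  for (g in groups$group) for (w in timepoints) {
    hit <- stage_table$group == g & stage_table$week == w
    if (sum(hit) != 1L)
      stop(sprintf("stage_table must give exactly one row for group '%s', week %s",
                   g, w), call. = FALSE)
  }
  if (any(stage_table$consolidation_fraction < 0 |
          stage_table$consolidation_fraction > 1))
    stop("consolidation fractions must lie in [0, 1]", call. = FALSE)
  if (histology_noise_sd < 0)
    stop("histology_noise_sd must be >= 0", call. = FALSE)
  if (is.null(mortality_prob))
    mortality_prob <- stats::setNames(rep(0, nrow(groups)), groups$group)
  if (any(!(groups$group %in% names(mortality_prob))))
    stop("mortality_prob must name every group", call. = FALSE)
  structure(list(groups = groups, timepoints = as.integer(timepoints),
                 stage_table = stage_table,
                 histology_noise_sd = histology_noise_sd,
                 mortality_prob = mortality_prob, assays = assays,
                 phantom = phantom, n_patch_seeds = as.integer(n_patch_seeds),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param n animals per arm.
#' @param grid_shape,spacing_mm forwarded to [phantom_config()].
#' @export
default_cohort_config <- function(n = 10L, rng_seed = 1L,
                                  grid_shape = c(128L, 128L, 96L),
                                  spacing_mm = c(0.25, 0.25, 0.25)) {
  groups <- data.frame(
    group = c("AMD3100", "PBS_sc", "MSX122", "DMSO_CD_ip"),
    treatment = c("AMD3100 10 mg/kg s.c.", "PBS s.c.",
                  "MSX-122 10 mg/kg i.p.", "10% DMSO/45% CD i.p."),
    matched_vehicle = c("PBS_sc", NA, "DMSO_CD_ip", NA),
    n = n, stringsAsFactors = FALSE)
  # vehicles reach week-20 consolidation; the effective drug holds fibrosis
  # at 30% of control, the marginal drug at 70% of control
  f20 <- 0.95
  stage_table <- data.frame(
    group = groups$group, week = 20L,
    consolidation_fraction = c(0.70 * f20, f20, 0.30 * f20, f20))
  assays <- list(
    list(assay = "CXCL12_serum", days = c(0, 1, 3, 7, 14, 28),
         mean_by_day = c(2.0, 3.5, 4.5, 5.0, 4.0, 3.0), sd = 0.4,
         n_replicates = 6L),
    list(assay = "CXCL12_BALF", days = c(0, 1, 3, 7, 14, 28),
         mean_by_day = c(0.5, 1.2, 2.0, 2.6, 2.2, 1.5), sd = 0.25,
         n_replicates = 6L),
    list(assay = "CXCR4_mRNA", days = c(0, 1, 3, 7, 14, 28),
         mean_by_day = c(1.0, 1.5, 2.2, 3.0, 2.5, 2.0), sd = 0.3,
         n_replicates = 5L))
  cohort_config(groups = groups, timepoints = 20L, stage_table = stage_table,
                histology_noise_sd = 0.5,
                mortality_prob = c(AMD3100 = 0.5, PBS_sc = 0, MSX122 = 0,
                                   DMSO_CD_ip = 0),
                assays = assays,
                phantom = phantom_config(grid_shape = grid_shape,
                                         spacing_mm = spacing_mm),
                rng_seed = rng_seed)
}

clamp_grade <- function(g) pmin(pmax(round(g), 0), 4)

#' Generate a cohort bundle on disk
#'
#' Simulates the whole study under one RNG stream seeded from the config:
#' per animal and timepoint a CT phantom (volume + mask NIfTI files),
#' histology slide grades tied to the consolidation fraction through
#' `grade = clamp(round(4 f + Normal(0, sd)), 0, 4)`, a survival table
#' (per-group Bernoulli death indicator, death week uniform over the study
#' when dead), assay timecourse tables, and a JSON manifest listing every
#' file and the seed. Identical config and seed reproduce the bundle
#' byte for byte.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param write_volumes write the NIfTI volume/mask pairs (set `FALSE` to
#'   keep the densitometry table but skip the large image files).
#' @param simulate_ct simulate CT phantoms at all; `FALSE` yields a
#'   tables-only bundle (histology, survival, timecourses) for work that
#'   exercises only the non-imaging layers.
#' @return invisibly, a list with the manifest and the generated tables.
#' @export
generate_cohort <- function(config, out_dir, write_volumes = TRUE,
                            simulate_ct = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop(sprintf("output path '%s' is not writable", out_dir), call. = FALSE)
  set.seed(config$rng_seed)

  files <- character()
  hist_rows <- list(); surv_rows <- list(); dens_rows <- list()
  labels <- side_labels(config$phantom$irradiated_side)

  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups$group[gi]
    for (a in seq_len(config$groups$n[gi])) {
      id <- sprintf("%s_%02d", g, a)
      dead <- stats::runif(1) < config$mortality_prob[[g]]
      death_week <- if (dead)
        sample.int(max(config$timepoints), 1L) else NA_integer_
      surv_rows[[length(surv_rows) + 1L]] <-
        data.frame(animal_id = id, group = g, death_week = death_week,
                   stringsAsFactors = FALSE)
      for (w in config$timepoints) {
        f <- config$stage_table$consolidation_fraction[
          config$stage_table$group == g & config$stage_table$week == w]
        if (simulate_ct) {
          pc <- config$phantom
          pc$stage <- stage_params(w, f, config$n_patch_seeds)
          pc$rng_seed <- NULL  # draw from the cohort stream
          ph <- generate_phantom(pc)
          if (write_volumes) {
            vf <- file.path(out_dir, sprintf("volume_%s_w%02d.nii.gz", id, w))
            mf <- file.path(out_dir, sprintf("mask_%s_w%02d.nii.gz", id, w))
            write_volume(ph$volume, vf)
            write_volume(ph$mask, mf)
            files <- c(files, vf, mf)
          }
          for (lab in labels) {
            ds <- summarize_densitometry(ph$volume, ph$mask, lab)
            dens_rows[[length(dens_rows) + 1L]] <-
              cbind(data.frame(animal_id = id, group = g, week = w),
                    as.data.frame(ds)[, -1, drop = FALSE])
          }
        }
        grades <- clamp_grade(4 * f +
          stats::rnorm(3, 0, config$histology_noise_sd))
        hist_rows[[length(hist_rows) + 1L]] <-
          data.frame(animal_id = id, group = g, week = w,
                     slide1 = grades[1], slide2 = grades[2],
                     slide3 = grades[3], stringsAsFactors = FALSE)
      }
    }
  }

  tc_rows <- list()
  for (as_ in config$assays) {
    for (di in seq_along(as_$days)) {
      v <- as_$mean_by_day[di] + stats::rnorm(as_$n_replicates, 0, as_$sd)
      tc_rows[[length(tc_rows) + 1L]] <-
        data.frame(assay = as_$assay, day = as_$days[di],
                   animal_id = sprintf("TC%02d", seq_len(as_$n_replicates)),
                   value = v, stringsAsFactors = FALSE)
    }
  }

  histology <- do.call(rbind, hist_rows)
  survival <- do.call(rbind, surv_rows)
  densitometry <- if (length(dens_rows)) do.call(rbind, dens_rows) else NULL
  timecourse <- if (length(tc_rows)) do.call(rbind, tc_rows) else
    data.frame(assay = character(), day = numeric(),
               animal_id = character(), value = numeric())

  write_table_csv(config$groups, file.path(out_dir, "cohort_groups.csv"))
  files <- c(files, file.path(out_dir, "cohort_groups.csv"))
  write_table_csv(histology, file.path(out_dir, "histology.csv"))
  write_table_csv(survival, file.path(out_dir, "survival.csv"))
  write_table_csv(timecourse, file.path(out_dir, "timecourse.csv"))
  files <- c(files, file.path(out_dir, c("histology.csv", "survival.csv",
                                         "timecourse.csv")))
  if (!is.null(densitometry)) {
    write_table_csv(densitometry, file.path(out_dir, "densitometry.csv"))
    files <- c(files, file.path(out_dir, "densitometry.csv"))
  }

  manifest <- list(generator = "fibrodens cohort simulator",
                   seed = config$rng_seed,
                   n_groups = nrow(config$groups),
                   n_animals = sum(config$groups$n),
                   timepoints = config$timepoints,
                   files = basename(files))
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(manifest = manifest, histology = histology,
                 survival = survival, timecourse = timecourse,
                 densitometry = densitometry, dir = out_dir))
}
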
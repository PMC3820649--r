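#' Per-group and drug-vs-vehicle summary tables
#'
#' The comparative layer of a study run. For every group: n, mortality,
#' endpoint PF score mean and SEM (survivors only), mean V_-200 and the
#' dual-criterion PF incidence. For every drug arm: histology- and
#' CT-based vehicle-normalized means, attenuation and Student's t against
#' the matched vehicle. Animals dead before the horizon contribute to
#' mortality but are excluded from endpoint fibrosis summaries.
#'
#' @param scores per-animal score table from [score_histology_table()].
#' @param densitometry per-animal densitometry table (needs `animal_id`,
#'   `group`, `week` and a `V_-200` column).
#' @param survival survival table (`animal_id, group, death_week`).
#' @param groups groups table as in [cohort_config()].
#' @param criteria a [pf_call_criteria()].
#' @param horizon_weeks endpoint week (default the latest scored week).
#' @param var_equal passed to [students_t_test()].
#' @return list with data.frames `group_summary` and `efficacy`.
#' @export
compute_efficacy_tables <- function(scores, densitometry, survival, groups,
                                    criteria = pf_call_criteria(),
                                    horizon_weeks = max(scores$week),
                                    var_equal = TRUE) {
  vcol <- grep("^V_-200$|^V_.200$", names(densitometry), value = TRUE)[1]
  if (is.na(vcol))
    stop("densitometry table carries no V_-200 column", call. = FALSE)

  endpoint <- function(tab) tab[tab$week == horizon_weeks, , drop = FALSE]
  sc <- endpoint(scores); de <- endpoint(densitometry)

  measurements <- function(g) {
    ids <- endpoint_survivors(survival, g, horizon_weeks)
    s <- sc[sc$group == g & sc$animal_id %in% ids, , drop = FALSE]
    d <- de[de$group == g & de$animal_id %in% ids, , drop = FALSE]
    d <- d[match(s$animal_id, d$animal_id), , drop = FALSE]
    list(ids = s$animal_id, total = s$total, v200 = d[[vcol]])
  }

  gs <- lapply(groups$group, function(g) {
    m <- measurements(g)
    grp <- score_group(m$total)
    calls <- classify_pf(m$total, m$v200, criteria)
    data.frame(group = g, n = groups$n[groups$group == g],
               n_endpoint = length(m$ids),
               mortality_percent = mortality(survival, g, horizon_weeks),
               mean_pf_score = grp$mean_total, sem_pf_score = grp$sem,
               mean_v200 = mean(m$v200),
               pf_incidence_percent = pf_incidence(calls),
               stringsAsFactors = FALSE)
  })
  group_summary <- do.call(rbind, gs)

  drug_rows <- which(!is.na(groups$matched_vehicle) &
                       groups$matched_vehicle != "")
  eff <- list()
  for (i in drug_rows) {
    g <- groups$group[i]; v <- groups$matched_vehicle[i]
    md <- measurements(g); mv <- measurements(v)
    for (readout in c("histology", "ct_v200")) {
      x <- if (readout == "histology") md$total else md$v200
      y <- if (readout == "histology") mv$total else mv$v200
      er <- efficacy_result(x, y, g, v, var_equal = var_equal)
      eff[[length(eff) + 1L]] <- data.frame(
        group = g, matched_vehicle = v, readout = readout,
        normalized_mean_percent = er$normalized_mean_percent,
        attenuation_percent = er$attenuation_percent,
        t_statistic = er$t_statistic,
        degrees_of_freedom = er$degrees_of_freedom,
        p_two_sided = er$p_two_sided,
        n_drug = er$n_drug, n_vehicle = er$n_vehicle,
        stringsAsFactors = FALSE)
    }
  }
  efficacy <- if (length(eff)) do.call(rbind, eff) else
    data.frame(group = character())

  list(group_summary = group_summary, efficacy = efficacy)
}

stage_log <- function(stage, ...) {
  message(sprintf("[fibrodens] %s: %s", stage, sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline: simulate, densitometry, score, efficacy, timecourse
#'
#' Orchestrates one reproducible study run. With `cohort` given, the
#' synthetic cohort is generated first; otherwise `in_dir` must contain a
#' previously generated (or externally assembled) bundle in the same CSV
#' dialect. Writes `summary.csv` (per-lung densitometry), `scores.csv`,
#' `groups.csv`, `efficacy.csv`, `timecourse_summary.csv` and an atomic
#' `run_manifest.json` carrying the seed, a config hash and md5 checksums
#' of every input and output. Re-running with the same config and inputs
#' reproduces identical numeric outputs.
#'
#' @param out_dir run output directory.
#' @param cohort optional [cohort_config()]; when given, simulation runs
#'   into `file.path(out_dir, "cohort")`.
#' @param in_dir directory holding an existing cohort bundle (ignored when
#'   `cohort` is given).
#' @param criteria a [pf_call_criteria()].
#' @param thresholds,quantiles extra densitometry thresholds/percentiles.
#' @param horizon_weeks endpoint week (default: latest week in the bundle).
#' @param write_volumes forwarded to [generate_cohort()].
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, in_dir = NULL,
                         criteria = pf_call_criteria(),
                         thresholds = -200, quantiles = 50,
                         horizon_weeks = NULL, write_volumes = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_config"))
    in_dir <- file.path(out_dir, "cohort")
    run_stage("simulate", {
      generate_cohort(cohort, in_dir, write_volumes = write_volumes)
      stage_log("simulate", "cohort of %d animals, seed %d",
                sum(cohort$groups$n), cohort$rng_seed)
    })
  }
  if (is.null(in_dir))
    stop("either a cohort config or an input directory is required",
         call. = FALSE)

  densitometry <- run_stage("densitometry", {
    path <- file.path(in_dir, "densitometry.csv")
    de <- if (file.exists(path)) {
      read_table_csv(path, c("animal_id", "group", "week"))
    } else {
      # no precomputed table: summarize every volume/mask pair in the bundle
      vols <- list.files(in_dir, pattern = "^volume_.*\\.nii(\\.gz)?$",
                         full.names = TRUE)
      if (length(vols) == 0L)
        stop(sprintf("no densitometry.csv and no volumes in '%s'", in_dir))
      rows <- lapply(vols, function(vf) {
        mf <- sub("volume_", "mask_", vf)
        vol <- read_volume(vf); msk <- read_mask(mf)
        info <- sub("^volume_(.*)_w(\\d+)\\..*$", "\\1|\\2", basename(vf))
        parts <- strsplit(info, "|", fixed = TRUE)[[1]]
        id <- parts[1]
        cbind(data.frame(animal_id = id,
                         group = sub("_[0-9]+$", "", id),
                         week = as.integer(parts[2])),
              as.data.frame(summarize_densitometry(
                vol, msk, 1L, thresholds, quantiles))[, -1, drop = FALSE])
      })
      do.call(rbind, rows)
    }
    stage_log("densitometry", "%d lung summaries", nrow(de))
    write_table_csv(de, file.path(out_dir, "summary.csv"))
    de
  })

  scores <- run_stage("score", {
    hist <- read_table_csv(file.path(in_dir, "histology.csv"),
                           c("animal_id", "group", "week",
                             "slide1", "slide2", "slide3"))
    sc <- score_histology_table(hist)
    stage_log("score", "%d animals scored", nrow(sc))
    write_table_csv(sc, file.path(out_dir, "scores.csv"))
    sc
  })

  eff <- run_stage("efficacy", {
    survival <- read_table_csv(file.path(in_dir, "survival.csv"),
                               c("animal_id", "group", "death_week"))
    gpath <- file.path(in_dir, "cohort_groups.csv")
    groups <- if (!is.null(cohort)) cohort$groups
      else if (file.exists(gpath))
        read_table_csv(gpath, c("group", "matched_vehicle", "n"))
      else infer_groups(scores, survival)
    hw <- if (is.null(horizon_weeks)) max(scores$week) else horizon_weeks
    tabs <- compute_efficacy_tables(scores, densitometry, survival, groups,
                                    criteria, hw)
    stage_log("efficacy", "%d groups, %d drug-vs-vehicle comparisons",
              nrow(tabs$group_summary), nrow(tabs$efficacy))
    write_table_csv(tabs$group_summary, file.path(out_dir, "groups.csv"))
    write_table_csv(tabs$efficacy, file.path(out_dir, "efficacy.csv"))
    tabs
  })

  run_stage("timecourse", {
    path <- file.path(in_dir, "timecourse.csv")
    if (file.exists(path)) {
      tc <- read_table_csv(path, c("assay", "day", "animal_id", "value"))
      if (nrow(tc)) {
        summaries <- lapply(unique(tc$assay), function(a)
          timecourse_summarize(tc, a))
        out <- do.call(rbind, summaries)
        stage_log("timecourse", "%d assays, %d day summaries",
                  length(unique(tc$assay)), nrow(out))
        write_table_csv(out, file.path(out_dir, "timecourse_summary.csv"))
      }
    }
  })

  outputs <- c("summary.csv", "scores.csv", "groups.csv", "efficacy.csv",
               "timecourse_summary.csv")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  inputs <- list.files(in_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  manifest <- list(
    tool = "fibrodens",
    version = as.character(utils::packageVersion("fibrodens")),
    config_hash = config_hash(list(criteria = unclass(criteria),
                                   thresholds = thresholds,
                                   quantiles = quantiles,
                                   seed = if (!is.null(cohort)) cohort$rng_seed)),
    seed = if (!is.null(cohort)) cohort$rng_seed,
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_atomic(manifest, file.path(out_dir, "run_manifest.json"))
  stage_log("run", "manifest written with %d outputs", length(outputs))
  invisible(manifest)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# groups table (group, matched_vehicle, n) recovered from run tables when
# the bundle carries no cohort_groups.csv; pairing falls back to the
# standard arm names of the default study layout
infer_groups <- function(scores, survival, pairing = NULL) {
  gs <- unique(scores$group)
  n <- vapply(gs, function(g) sum(survival$group == g), integer(1))
  mv <- rep(NA_character_, length(gs))
  default_pairs <- c(AMD3100 = "PBS_sc", MSX122 = "DMSO_CD_ip")
  for (i in seq_along(gs)) {
    cand <- if (!is.null(pairing)) pairing[[gs[i]]]
      else if (gs[i] %in% names(default_pairs)) default_pairs[[gs[i]]]
      else NA_character_
    if (!is.null(cand) && !is.na(cand) && cand %in% gs) mv[i] <- cand
  }
  data.frame(group = gs, treatment = gs, matched_vehicle = mv, n = n,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a markdown report of a pipeline run
#'
#' Emits one human-readable summary of a run directory: group table,
#' drug-vs-vehicle efficacy, and a coarse density-curve table per group
#' (mean V_T at a handful of thresholds).
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param out_md output markdown path (default `report.md` inside the run).
#' @return invisibly, the report path.
#' @export
write_report <- function(run_dir, out_md = file.path(run_dir, "report.md")) {
  md <- c("# fibrodens run report", "")
  fmt_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"),
        character(1)))
  }
  for (f in c("groups.csv", "efficacy.csv", "timecourse_summary.csv")) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) {
      md <- c(md, paste0("## ", sub("\\.csv$", "", f)), "",
              fmt_table(utils::read.csv(p)), "")
    }
  }
  p <- file.path(run_dir, "summary.csv")
  if (file.exists(p)) {
    de <- utils::read.csv(p, check.names = FALSE)
    vcols <- grep("^V_|^HU_", names(de), value = TRUE)
    agg <- stats::aggregate(de[vcols], by = list(group = de$group), FUN = mean)
    md <- c(md, "## mean densitometry by group", "", fmt_table(agg), "")
  }
  writeLines(md, out_md)
  invisible(out_md)
}
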
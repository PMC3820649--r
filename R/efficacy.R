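#' Unpaired two-sample Student's t-test
#'
#' Pooled-variance (equal-variance) two-sample t-test, two-sided — the
#' classical Student form, with Welch's unequal-variance correction
#' available behind `var_equal = FALSE`. A zero pooled variance (both
#' groups constant) leaves the statistic undefined and is an error rather
#' than a silent p of NaN.
#'
#' @param x,y numeric measurement vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test if `TRUE` (default),
#'   Welch if `FALSE`.
#' @return list with `t`, `df` and `p` (two-sided).
#' @export
students_t_test <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("measurements must be finite", call. = FALSE)
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled <= 0)
    stop("degenerate variance: both groups are constant, t is undefined",
         call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Normalize a drug group to its matched vehicle control
#'
#' Expresses the drug-group mean fibrosis measurement (histology total or
#' CT V_-200) as a percent of its matched vehicle-control mean, the
#' vehicle thereby being 100%. Drug arms are always compared to their own
#' matched vehicle, never to pooled controls.
#'
#' @param drug,vehicle numeric per-animal measurements.
#' @return percent of control.
#' @export
normalize_to_control <- function(drug, vehicle) {
  drug <- as.numeric(drug); vehicle <- as.numeric(vehicle)
  if (length(drug) == 0L || length(vehicle) == 0L)
    stop("both groups need at least one measurement", call. = FALSE)
  if (any(!is.finite(drug)) || any(!is.finite(vehicle)))
    stop("measurements must be finite", call. = FALSE)
  vm <- mean(vehicle)
  if (vm <= 0)
    stop("normalization error: vehicle mean must be positive", call. = FALSE)
  100 * mean(drug) / vm
}

#' Percent attenuation of fibrosis by a drug
#'
#' `100 - normalize_to_control(drug, vehicle)`: how much of the
#' vehicle-level fibrosis the treatment prevented, in percent. Negative
#' values mean the drug group exceeded its control.
#'
#' @inheritParams normalize_to_control
#' @export
attenuation <- function(drug, vehicle) {
  100 - normalize_to_control(drug, vehicle)
}

#' Dual-criterion pulmonary-fibrosis call criteria
#'
#' An animal is called PF-positive only when *both* readouts agree:
#' trichrome histology at or above `histology_cut` (default the 12-point
#' maximum, i.e. staining-positive throughout) *and* CT V_-200 at or above
#' `v200_cut` percent. The default CT cut of 10% sits just above the
#' normal-lung range (V_-200 under 5% unirradiated, under 10% at 12
#' weeks), the smallest cut separating normal from fibrotic lungs.
#'
#' @param histology_cut required PF total, in 0..12.
#' @param v200_cut required V_-200 percent, in 0..100.
#' @export
pf_call_criteria <- function(histology_cut = 12, v200_cut = 10) {
  if (histology_cut < 0 || histology_cut > 12)
    stop("histology_cut must lie in [0, 12]", call. = FALSE)
  if (v200_cut < 0 || v200_cut > 100)
    stop("v200_cut must lie in [0, 100]", call. = FALSE)
  structure(list(histology_cut = histology_cut, v200_cut = v200_cut),
            class = "pf_call_criteria")
}

#' Classify animals as PF-positive
#'
#' Vectorized conjunction of the two criteria.
#'
#' @param histology_total per-animal PF totals (0..12).
#' @param v200 per-animal V_-200 percents.
#' @param criteria a [pf_call_criteria()].
#' @return logical vector of PF calls.
#' @export
classify_pf <- function(histology_total, v200, criteria = pf_call_criteria()) {
  stopifnot(inherits(criteria, "pf_call_criteria"))
  histology_total >= criteria$histology_cut & v200 >= criteria$v200_cut
}

#' PF incidence of a group
#' @param calls logical PF calls from [classify_pf()].
#' @return percent of PF-positive animals, in `[0, 100]`.
#' @export
pf_incidence <- function(calls) {
  if (length(calls) == 0L) stop("empty group", call. = FALSE)
  100 * sum(calls) / length(calls)
}

#' Group mortality by a horizon
#'
#' Percent of a group's animals dead at or before `horizon_weeks`, from a
#' survival table with columns `animal_id, group, death_week` (NA or empty
#' for animals alive at study end). Animals dead before the endpoint are
#' reported here and excluded from endpoint fibrosis summaries (see
#' [endpoint_survivors()]).
#'
#' @param survival survival table data.frame.
#' @param group group name.
#' @param horizon_weeks study horizon (default 20 weeks).
#' @return percent mortality.
#' @export
mortality <- function(survival, group, horizon_weeks = 20) {
  rows <- survival[survival$group == group, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("unknown group '%s' in survival table", group), call. = FALSE)
  dead <- !is.na(rows$death_week) & rows$death_week <= horizon_weeks
  100 * sum(dead) / nrow(rows)
}

#' @rdname mortality
#' @return for `endpoint_survivors`, the animal ids alive past the horizon.
#' @export
endpoint_survivors <- function(survival, group, horizon_weeks = 20) {
  rows <- survival[survival$group == group, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("unknown group '%s' in survival table", group), call. = FALSE)
  alive <- is.na(rows$death_week) | rows$death_week > horizon_weeks
  rows$animal_id[alive]
}

#' Drug-vs-vehicle efficacy result
#'
#' The full comparative readout for one drug arm against its matched
#' vehicle: vehicle-normalized mean, percent attenuation, pooled-variance
#' t-test, and group sizes.
#'
#' @param drug,vehicle numeric per-animal fibrosis measurements.
#' @param drug_name,vehicle_name group labels carried into the result.
#' @param var_equal passed to [students_t_test()].
#' @return list of class `efficacy_result`.
#' @export
efficacy_result <- function(drug, vehicle, drug_name = "drug",
                            vehicle_name = "vehicle", var_equal = TRUE) {
  norm <- normalize_to_control(drug, vehicle)
  tt <- students_t_test(drug, vehicle, var_equal = var_equal)
  structure(list(group = drug_name, matched_vehicle = vehicle_name,
                 normalized_mean_percent = norm,
                 attenuation_percent = 100 - norm,
                 t_statistic = tt$t, degrees_of_freedom = tt$df,
                 p_two_sided = tt$p,
                 n_drug = length(drug), n_vehicle = length(vehicle)),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("<efficacy_result> %s vs %s (n = %d vs %d)\n",
              x$group, x$matched_vehicle, x$n_drug, x$n_vehicle))
  cat(sprintf("  normalized mean: %.1f%% of control; attenuation: %.1f%%\n",
              x$normalized_mean_percent, x$attenuation_percent))
  cat(sprintf("  Student t = %.3f, df = %g, two-sided p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_sided))
  invisible(x)
}

#' Baseline-anchored assay timecourse summary
#'
#' Summarizes a repeated-measurement assay (ELISA concentrations, RNase
#' protection mRNA levels, flow percentages) across days, anchored at the
#' baseline day: per-day mean and SEM, the relative level (day mean over
#' baseline mean, so day 0 is 1 by construction), and a per-day
#' significance flag from the unpaired Student's t-test against the
#' baseline replicates at `alpha`. When a `reference` column is present
#' (e.g. actin for normalized mRNA), each replicate is first divided by
#' its paired reference value. No multiple-testing correction is applied
#' across days. A day with zero pooled variance against the baseline cannot
#' be tested: equal means report p = 1, unequal means report `NA`, and
#' neither is flagged significant.
#'
#' @param table long data.frame with columns `assay, day, animal_id, value`
#'   and optionally `reference`.
#' @param assay assay name to summarize.
#' @param baseline_day anchor day (default 0); must have >= 2 replicates.
#' @param alpha significance level for the per-day flag.
#' @param var_equal passed to [students_t_test()].
#' @return data.frame of class `timecourse_summary`, one row per day:
#'   `assay, day, n, mean, sem, relative_level, p_vs_baseline,
#'   significant_vs_baseline`.
#' @export
timecourse_summarize <- function(table, assay, baseline_day = 0,
                                 alpha = 0.05, var_equal = TRUE) {
  need <- c("assay", "day", "animal_id", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("timecourse table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- table[table$assay == assay, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("assay '%s' not present in table", assay), call. = FALSE)
  vals <- rows$value
  if ("reference" %in% names(rows) && any(!is.na(rows$reference))) {
    if (any(is.na(rows$reference) | rows$reference <= 0))
      stop("reference values must be positive wherever present", call. = FALSE)
    vals <- vals / rows$reference
  }
  days <- sort(unique(rows$day))
  if (!(baseline_day %in% days))
    stop(sprintf("baseline day %s missing from assay '%s'", baseline_day, assay),
         call. = FALSE)
  base <- vals[rows$day == baseline_day]
  if (length(base) < 2L)
    stop("baseline day needs at least 2 replicates", call. = FALSE)
  base_mean <- mean(base)
  if (base_mean == 0)
    stop("baseline mean is zero; relative levels undefined", call. = FALSE)

  out <- lapply(days, function(d) {
    v <- vals[rows$day == d]
    if (d != baseline_day && length(v) < 2L)
      stop(sprintf("day %s has fewer than 2 replicates", d), call. = FALSE)
    p <- if (d == baseline_day) NA_real_
         else tryCatch(students_t_test(v, base, var_equal = var_equal)$p,
                       error = function(e) {
                         # zero pooled variance: identical constant groups
                         # show no difference; otherwise p is undefined
                         if (isTRUE(all.equal(mean(v), mean(base)))) 1
                         else NA_real_
                       })
    data.frame(assay = assay, day = d, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               relative_level = mean(v) / base_mean,
               p_vs_baseline = p,
               significant_vs_baseline = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("timecourse_summary", "data.frame")
  out
}
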
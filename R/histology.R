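#' Per-animal fibrosis score from three slide grades
#'
#' Trichrome-stained slides are graded for fibrosis severity from 0
#' (normal) to 4 (grade IV, no airspace); three slides per animal (middle
#' of the lung, 50 um above and below) are summed into the per-animal PF
#' score, maximum 12 points = 100%.
#'
#' @param grades integer vector of exactly 3 slide grades, each in 0..4.
#' @return list of class `animal_histology_score` with `total` (0-12) and
#'   `percent_of_max` (0-100).
#' @export
score_animal <- function(grades) {
  grades <- as.numeric(grades)
  if (length(grades) != 3L)
    stop("exactly 3 slide grades per animal are required", call. = FALSE)
  if (any(!is.finite(grades)) || any(grades != round(grades)) ||
      any(grades < 0) || any(grades > 4))
    stop("slide grades must be integers in 0..4 (0 normal .. IV severe)",
         call. = FALSE)
  total <- as.integer(sum(grades))
  structure(list(total = total, percent_of_max = 100 * total / 12),
            class = "animal_histology_score")
}

#' @export
print.animal_histology_score <- function(x, ...) {
  cat(sprintf("PF score %d / 12 (%.1f%% of maximum)\n",
              x$total, x$percent_of_max))
  invisible(x)
}

#' Group summary of per-animal PF scores
#'
#' Mean and standard error of the per-animal totals. SEM uses the n-1
#' sample standard deviation and is reported as 0 for a single animal.
#'
#' @param grades_list list of 3-grade vectors (one per animal), or a
#'   numeric vector of already-summed totals.
#' @return list with `mean_total`, `sem` and `n`.
#' @export
score_group <- function(grades_list) {
  if (is.list(grades_list)) {
    totals <- vapply(grades_list, function(g) score_animal(g)$total, numeric(1))
  } else {
    totals <- as.numeric(grades_list)
    if (any(totals < 0) || any(totals > 12))
      stop("per-animal totals must lie in 0..12", call. = FALSE)
  }
  n <- length(totals)
  if (n == 0L) stop("empty group", call. = FALSE)
  list(mean_total = mean(totals),
       sem = if (n == 1L) 0 else stats::sd(totals) / sqrt(n),
       n = n)
}

#' Score a histology table animal by animal
#'
#' Applies [score_animal()] to each row of the cohort histology table
#' (columns `animal_id, group, week, slide1, slide2, slide3`).
#'
#' @param histology data.frame in the histology.csv dialect.
#' @return data.frame with `animal_id, group, week, total, percent_of_max`.
#' @export
score_histology_table <- function(histology) {
  need <- c("animal_id", "group", "week", "slide1", "slide2", "slide3")
  miss <- setdiff(need, names(histology))
  if (length(miss))
    stop("histology table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  scores <- lapply(seq_len(nrow(histology)), function(i)
    score_animal(unlist(histology[i, c("slide1", "slide2", "slide3")])))
  data.frame(animal_id = histology$animal_id, group = histology$group,
             week = histology$week,
             total = vapply(scores, `[[`, integer(1), "total"),
             percent_of_max = vapply(scores, `[[`, numeric(1), "percent_of_max"),
             stringsAsFactors = FALSE)
}
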
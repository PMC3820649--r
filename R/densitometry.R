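#' Extract the HU sample of one lung
#'
#' Pulls the Hounsfield-unit values of exactly the voxels carrying the
#' requested mask label, together with the physical voxel volume — the
#' masked-lung sample all densitometric readouts are computed from.
#'
#' @param volume a [voxel_volume()].
#' @param mask a co-registered [lung_mask()].
#' @param label lung selector (1 = right, 2 = left).
#' @return An object of class `hu_sample`: list with `values`,
#'   `voxel_volume_mm3` and `n`.
#' @export
extract_hu <- function(volume, mask, label = 1L) {
  check_same_grid(volume, mask)
  idx <- which(mask == as.integer(label))
  if (length(idx) == 0L)
    stop(sprintf("empty mask: no voxels carry label %s", label), call. = FALSE)
  hu_sample(as.numeric(volume)[idx], voxel_volume_mm3(volume))
}

#' @rdname extract_hu
#' @param values numeric HU values of the masked voxels.
#' @param voxel_volume_mm3 physical volume of one voxel, mm^3 (> 0).
#' @export
hu_sample <- function(values, voxel_volume_mm3 = 1) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("an HU sample needs at least one finite value", call. = FALSE)
  if (voxel_volume_mm3 <= 0)
    stop("voxel_volume_mm3 must be positive", call. = FALSE)
  structure(list(values = values, voxel_volume_mm3 = voxel_volume_mm3,
                 n = length(values)),
            class = "hu_sample")
}

#' @export
print.hu_sample <- function(x, ...) {
  cat(sprintf("<hu_sample> n = %d voxels, %.3g mm^3 each (lung volume %.4g mm^3)\n",
              x$n, x$voxel_volume_mm3, x$n * x$voxel_volume_mm3))
  invisible(x)
}

#' Percent of lung volume at or above an HU threshold (V_T)
#'
#' `100 * #\{v >= T\} / n`: the percent of the masked lung whose density is
#' at or above the threshold. At T = -200 HU this is the V_-200 fibrosis
#' marker. Percents are voxel-count based; under the uniform spacing of a
#' single acquisition this equals the physical-volume fraction.
#'
#' @param sample an [hu_sample()].
#' @param threshold HU threshold T.
#' @return percent in `[0, 100]`.
#' @export
percent_volume_at_or_above <- function(sample, threshold = -200) {
  stopifnot(inherits(sample, "hu_sample"))
  100 * sum(sample$values >= threshold) / sample$n
}

#' Cumulative HU density curve
#'
#' For each threshold of an ascending HU grid, the percent of lung volume
#' at or above it — the HU-versus-%volume plot read off whole-lung CT.
#' Implemented via one sort plus binary search over the grid.
#'
#' @param sample an [hu_sample()].
#' @param grid strictly ascending numeric HU thresholds (default -1000 to
#'   +200 in 10-HU steps).
#' @return An object of class `density_curve`: data.frame with columns
#'   `threshold_hu` and `percent_at_or_above`.
#' @export
density_curve <- function(sample, grid = seq(-1000, 200, by = 10)) {
  stopifnot(inherits(sample, "hu_sample"))
  if (length(grid) == 0L) stop("threshold grid is empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("threshold grid must be strictly ascending", call. = FALSE)
  sv <- sort(sample$values)
  n <- sample$n
  below <- findInterval(grid, sv, left.open = TRUE)  # count of values < T
  out <- data.frame(threshold_hu = grid,
                    percent_at_or_above = 100 * (n - below) / n)
  class(out) <- c("density_curve", "data.frame")
  out
}

#' HU percentile of a lung sample
#'
#' Linear-interpolation percentile (type-7 quantile) of the masked HU
#' values; `hu_percentile(s, 50)` is the lung median HU_50, which shifts
#' upward as fibrosis consolidates tissue.
#'
#' @param sample an [hu_sample()].
#' @param q percentile in `(0, 100)`.
#' @return HU value.
#' @export
hu_percentile <- function(sample, q = 50) {
  stopifnot(inherits(sample, "hu_sample"))
  if (any(q <= 0) || any(q >= 100))
    stop("q must lie strictly between 0 and 100", call. = FALSE)
  stats::quantile(sample$values, probs = q / 100, type = 7, names = FALSE)
}

#' Whole-lung densitometry summary
#'
#' Aggregates the densitometric readouts of one masked lung: threshold
#' volume fractions (always including V_-200), HU percentiles (always
#' including HU_50), lung volume and voxel count.
#'
#' @param volume a [voxel_volume()].
#' @param mask a co-registered [lung_mask()].
#' @param label lung selector.
#' @param thresholds HU thresholds for V_T (T = -200 is always added).
#' @param quantiles percentiles for HU_q (q = 50 is always added).
#' @return An object of class `densitometry_summary`: list with `v_map`
#'   (named percent per threshold), `percentiles` (named HU per q),
#'   `lung_volume_mm3` and `n_voxels`.
#' @export
summarize_densitometry <- function(volume, mask, label = 1L,
                                   thresholds = -200, quantiles = 50) {
  sample <- extract_hu(volume, mask, label)
  thresholds <- sort(unique(c(as.numeric(thresholds), -200)))
  quantiles <- sort(unique(c(as.numeric(quantiles), 50)))
  v_map <- vapply(thresholds, function(T)
    percent_volume_at_or_above(sample, T), numeric(1))
  names(v_map) <- format_hu_names(thresholds)
  pct <- vapply(quantiles, function(q) hu_percentile(sample, q), numeric(1))
  names(pct) <- paste0("HU_", format(quantiles, trim = TRUE))
  structure(list(label = as.integer(label), v_map = v_map, percentiles = pct,
                 lung_volume_mm3 = sample$n * sample$voxel_volume_mm3,
                 n_voxels = sample$n),
            class = "densitometry_summary")
}

format_hu_names <- function(thresholds) {
  paste0("V_", format(thresholds, trim = TRUE, scientific = FALSE))
}

#' @export
print.densitometry_summary <- function(x, ...) {
  cat(sprintf("<densitometry_summary> lung label %d: %d voxels, %.4g mm^3\n",
              x$label, x$n_voxels, x$lung_volume_mm3))
  for (nm in names(x$v_map))
    cat(sprintf("  %s = %.2f%%\n", nm, x$v_map[[nm]]))
  for (nm in names(x$percentiles))
    cat(sprintf("  %s = %.1f HU\n", nm, x$percentiles[[nm]]))
  invisible(x)
}

#' One-row data.frame of a densitometry summary (CSV dialect of the pipeline)
#' @param x a `densitometry_summary`.
#' @param animal_id optional id prepended as a column.
#' @export
as.data.frame.densitometry_summary <- function(x, row.names = NULL, optional = FALSE,
                                               animal_id = NA_character_, ...) {
  out <- data.frame(animal_id = animal_id, label = x$label,
                    n_voxels = x$n_voxels, lung_volume_mm3 = x$lung_volume_mm3,
                    stringsAsFactors = FALSE)
  for (nm in names(x$v_map)) out[[nm]] <- x$v_map[[nm]]
  for (nm in names(x$percentiles)) out[[nm]] <- x$percentiles[[nm]]
  out
}
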
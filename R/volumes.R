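#' Voxel volume and lung mask containers
#'
#' A `voxel_volume` is a 3D numeric array of Hounsfield units (HU) with a
#' physical voxel spacing in millimetres attached; a `lung_mask` is a
#' co-registered integer label array on the same grid (0 = background,
#' 1 = right lung, 2 = left lung). Both are plain arrays with a `spacing`
#' attribute, so all of base R's array machinery applies.
#'
#' @param x 3D array. For masks, values must be non-negative integers.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @return An object of class `voxel_volume` (or `lung_mask`).
#' @export
voxel_volume <- function(x, spacing) {
  if (length(dim(x)) != 3L)
    stop("a voxel volume must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths in mm", call. = FALSE)
  structure(x, spacing = spacing, class = c("voxel_volume", "array"))
}

#' @rdname voxel_volume
#' @export
lung_mask <- function(x, spacing) {
  if (length(dim(x)) != 3L)
    stop("a lung mask must be a 3D array", call. = FALSE)
  v <- as.vector(x)
  if (any(v < 0) || any(v != round(v)))
    stop("mask values must be non-negative integer labels", call. = FALSE)
  storage.mode(x) <- "integer"
  out <- voxel_volume(x, spacing)
  class(out) <- c("lung_mask", class(out))
  out
}

#' Voxel spacing of a volume or mask
#' @param x a `voxel_volume` or `lung_mask`.
#' @return numeric length-3 spacing in mm.
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) stop("object carries no voxel spacing", call. = FALSE)
  s
}

#' Physical volume of one voxel in mm^3
#' @inheritParams spacing
#' @export
voxel_volume_mm3 <- function(x) prod(spacing(x))

# shared grid check used throughout the pipeline
check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dim(volume), collapse = "x"),
                 paste(dim(mask), collapse = "x")), call. = FALSE)
  if (!isTRUE(all.equal(spacing(volume), spacing(mask))))
    stop("volume and mask voxel spacings differ", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x); s <- spacing(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], s[1], s[2], s[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x)
  tab <- table(as.vector(x))
  cat(sprintf("<lung_mask> %d x %d x %d voxels; labels: %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}
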
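#' Read and write CT volumes and masks (NIfTI-1)
#'
#' Volumes and masks travel as NIfTI-1 files (.nii or .nii.gz) with an
#' axis-aligned affine derived from the voxel spacing; masks are written
#' as unsigned 8-bit labels. Voxel indices are treated as 0-based grid
#' coordinates and world coordinates come from the spacing alone — oblique
#' affines are out of scope.
#'
#' @param path file path; unreadable or truncated files raise an error
#'   naming the path.
#' @return `read_volume` returns a [voxel_volume()]; `read_mask` a
#'   [lung_mask()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume: '%s' does not exist", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
    stop(sprintf("not a readable NIfTI-1 file: '%s' (%s)",
                 path, conditionMessage(e)), call. = FALSE))
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("missing or invalid voxel spacing in '%s'", path),
         call. = FALSE)
  voxel_volume(arr, sp[1:3])
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  m <- unclass(v)
  attr(m, "spacing") <- NULL
  storage.mode(m) <- "integer"
  lung_mask(m, spacing(v))
}

#' @rdname read_volume
#' @param x a [voxel_volume()] or [lung_mask()] to write.
#' @export
write_volume <- function(x, path) {
  arr <- unclass(x)
  attr(arr, "spacing") <- NULL
  is_mask <- inherits(x, "lung_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing(x)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' DICOM stored-value to Hounsfield-unit rescale
#'
#' CT DICOM series store raw integers that map to HU through the linear
#' rescale `HU = slope * stored + intercept` (tags RescaleSlope /
#' RescaleIntercept; typically slope 1, intercept -1024). This helper
#' performs that arithmetic for values imported from DICOM tooling.
#'
#' @param stored raw stored values.
#' @param slope,intercept rescale parameters.
#' @return Hounsfield units.
#' @export
dicom_rescale <- function(stored, slope = 1, intercept = -1024) {
  slope * as.numeric(stored) + intercept
}

# CSV dialect used throughout: comma-separated, UTF-8, header row, "."
# decimal separator -- i.e. plain read.csv/write.csv.
read_table_csv <- function(path, required = character()) {
  if (!file.exists(path))
    stop(sprintf("cannot read table: '%s' does not exist", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(sprintf("'%s' is missing columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  tab
}

write_table_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# atomic JSON write: temp file in the same directory, then rename
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
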
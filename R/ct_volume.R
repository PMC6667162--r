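#' CT volume in Hounsfield units
#'
#' Container for a 3D CT image. Voxels hold Hounsfield units (HU): air is
#' close to -1000, water 0, cortical bone above 1000. Raw scanner exports are
#' integer-valued with a -1024 floor; after a cross-calibration correction
#' ([apply_hu_correction()]) values are kept real-valued.
#'
#' Arrays are indexed `(row, col, slice)`. The display convention for the
#' in-plane axes is radiological by default: the patient's right side appears
#' at low column indices (image left).
#'
#' @param voxels 3D numeric array of HU.
#' @param spacing numeric length-3, voxel spacing in mm along (row, col,
#'   slice).
#' @param slice_axis index of the through-plane axis; the constructor only
#'   supports the canonical 3.
#' @param scanner_id,kernel_id free-text acquisition tags used to look up
#'   HU corrections.
#' @param patient_side `"radiological"` (patient right = image left, the
#'   default) or `"neurological"`.
#' @return An object of class `ct_volume`.
#' @seealso [read_volume()], [apply_calibration()], [make_scan()]
#' @export
ct_volume <- function(voxels, spacing, slice_axis = 3L,
                      scanner_id = "unknown", kernel_id = "standard",
                      patient_side = c("radiological", "neurological")) {
  patient_side <- match.arg(patient_side)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (length(voxels) == 0L)
    stop("`voxels` must be non-empty", call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("`voxels` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  if (!identical(as.integer(slice_axis), 3L))
    stop("only slice_axis = 3 (row, col, slice) is supported", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, slice_axis = 3L,
         scanner_id = as.character(scanner_id),
         kernel_id = as.character(kernel_id),
         patient_side = patient_side),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]; scanner '%s', kernel '%s', %s convention\n",
              min(x$voxels), max(x$voxels), x$scanner_id, x$kernel_id,
              x$patient_side))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Calibrated BMD volume
#'
#' A CT volume after HU-to-BMD conversion. Voxels are real-valued CaHA
#' equivalent densities in mg/cm^3; shape and spacing match the source
#' [ct_volume()] and the [calibration_function()] used is retained as
#' provenance.
#'
#' @param voxels 3D numeric array of BMD (mg/cm^3 CaHA).
#' @param spacing voxel spacing in mm, as in [ct_volume()].
#' @param provenance the `calibration_function` that produced the values.
#' @return An object of class `bmd_volume`.
#' @export
bmd_volume <- function(voxels, spacing, provenance = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("`voxels` must be a non-empty 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  if (!is.null(provenance) && !inherits(provenance, "calibration_function"))
    stop("`provenance` must be a calibration_function", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, provenance = provenance),
            class = "bmd_volume")
}

#' @export
print.bmd_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bmd_volume> %d x %d x %d voxels, BMD range [%.1f, %.1f] mg/cm^3 CaHA\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  if (!is.null(x$provenance))
    cat(sprintf("  calibrated by: %s\n", format(x$provenance)))
  invisible(x)
}

#' @export
dim.bmd_volume <- function(x) dim(x$voxels)
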
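#' Affine HU-BMD calibration function
#'
#' An affine map between Hounsfield units and CaHA-equivalent BMD. Two fit
#' conventions are in use in the QCT literature and both appear here, so the
#' direction is an explicit field rather than an implicit assumption:
#'
#' * `bmd_on_hu`: `BMD = slope * HU + intercept` (the convention of the
#'   phantom and non-patient-specific calibrations; slope ~ 0.8).
#' * `hu_on_bmd`: `HU = slope * BMD + intercept` (the convention in which
#'   the air-fat-muscle fit is reported; slope ~ 1.2). Evaluation inverts
#'   the map, `BMD = (HU - intercept) / slope`.
#'
#' In either convention the implied dBMD/dHU must be positive: denser tissue
#' attenuates more.
#'
#' @param slope,intercept affine coefficients in the stated convention.
#' @param fit_direction `"bmd_on_hu"` or `"hu_on_bmd"`.
#' @param method which calibration produced the map: `"phantom"`, `"afm"`,
#'   `"nps"`, or `"truth"` (synthetic ground truth).
#' @param units density units; only `"mg/cm^3 CaHA"` is used.
#' @param r_squared optional R^2 of the underlying fit.
#' @param provenance optional free-form list describing how the map was
#'   obtained (number of rods/scans, slices, seeds, ...).
#' @return An object of class `calibration_function`.
#' @examples
#' cal <- calibration_function(0.82, -4.2, "bmd_on_hu", "nps")
#' bmd_from_hu(cal, c(0, 1000))
#' @export
calibration_function <- function(slope, intercept,
                                 fit_direction = c("bmd_on_hu", "hu_on_bmd"),
                                 method = c("phantom", "afm", "nps", "truth"),
                                 units = "mg/cm^3 CaHA",
                                 r_squared = NULL, provenance = NULL) {
  fit_direction <- match.arg(fit_direction)
  method <- match.arg(method)
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)
  if (length(slope) != 1L || length(intercept) != 1L ||
      !is.finite(slope) || !is.finite(intercept))
    stop("`slope` and `intercept` must be finite scalars", call. = FALSE)
  if (slope == 0)
    stop("calibration slope must be non-zero", call. = FALSE)
  # dBMD/dHU = slope (bmd_on_hu) or 1/slope (hu_on_bmd): positive either way
  if (slope < 0)
    stop("calibration must be strictly increasing (dBMD/dHU > 0), got slope ",
         slope, call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept, fit_direction = fit_direction,
         method = method, units = units,
         r_squared = if (is.null(r_squared)) NULL else as.numeric(r_squared),
         provenance = provenance),
    class = "calibration_function"
  )
}

#' @export
format.calibration_function <- function(x, ...) {
  eq <- if (x$fit_direction == "bmd_on_hu")
    sprintf("BMD = %.6g * HU + %.6g", x$slope, x$intercept)
  else
    sprintf("HU = %.6g * BMD + %.6g", x$slope, x$intercept)
  sprintf("%s calibration [%s]", x$method, eq)
}

#' @export
print.calibration_function <- function(x, ...) {
  cat("<calibration_function>", format(x), "\n")
  cat("  units:", x$units)
  if (!is.null(x$r_squared)) cat(sprintf("; R^2 = %.6f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Evaluate a calibration function
#'
#' `bmd_from_hu()` maps HU to BMD honouring the stored fit direction;
#' `hu_from_bmd()` is its exact inverse.
#'
#' @param cal a [calibration_function()].
#' @param hu,bmd numeric vectors/arrays.
#' @return numeric of the same shape as the input.
#' @export
bmd_from_hu <- function(cal, hu) {
  stopifnot(inherits(cal, "calibration_function"))
  if (cal$fit_direction == "bmd_on_hu") cal$slope * hu + cal$intercept
  else (hu - cal$intercept) / cal$slope
}

#' @rdname bmd_from_hu
#' @export
hu_from_bmd <- function(cal, bmd) {
  stopifnot(inherits(cal, "calibration_function"))
  if (cal$fit_direction == "bmd_on_hu") (bmd - cal$intercept) / cal$slope
  else cal$slope * bmd + cal$intercept
}

#' Convert a CT volume to BMD
#'
#' Applies an affine calibration voxel-wise. Output densities are kept
#' real-valued; shape and spacing are preserved.
#'
#' @param vol a [ct_volume()].
#' @param cal a [calibration_function()].
#' @return A [bmd_volume()] with `cal` recorded as provenance.
#' @examples
#' v <- ct_volume(array(0L, c(2, 2, 1)), c(1, 1, 3))
#' apply_calibration(v, nps_preset())$voxels[1, 1, 1]  # -4.2
#' @export
apply_calibration <- function(vol, cal) {
  stopifnot(inherits(vol, "ct_volume"), inherits(cal, "calibration_function"))
  out <- bmd_from_hu(cal, vol$voxels)
  bmd_volume(out, vol$spacing, provenance = cal)
}

#' Cohort-average non-patient-specific calibration preset
#'
#' The packaged non-patient-specific (NPS) map, `BMD = 0.82 * HU - 4.2`,
#' obtained by averaging per-scan phantom calibration functions from a
#' single-scanner reference cohort. It is applied unchanged to every scan,
#' so it cannot absorb scanner- or kernel-specific HU shifts; see
#' [calibrate_afm()] for the patient-specific alternative.
#'
#' @return A [calibration_function()] with method `"nps"`.
#' @export
nps_preset <- function() {
  calibration_function(0.82, -4.2, "bmd_on_hu", "nps",
                       provenance = list(source = "reference-cohort average"))
}

#' Serialize / parse calibration functions as JSON
#'
#' `serialize_calibration()` renders a [calibration_function()] as a JSON
#' record (optionally written to `path`); `parse_calibration()` restores it.
#' The round trip is lossless for slope, intercept, fit direction, method
#' and units.
#'
#' @param cal a [calibration_function()].
#' @param path optional file to write to / read from.
#' @param text JSON text (ignored when `path` is given).
#' @return `serialize_calibration()` returns the JSON string invisibly when
#'   writing to a file, visibly otherwise; `parse_calibration()` returns a
#'   `calibration_function`.
#' @export
serialize_calibration <- function(cal, path = NULL) {
  stopifnot(inherits(cal, "calibration_function"))
  rec <- list(slope = cal$slope, intercept = cal$intercept,
              fit_direction = cal$fit_direction, method = cal$method,
              units = cal$units)
  if (!is.null(cal$r_squared)) rec$r_squared <- cal$r_squared
  if (!is.null(cal$provenance)) rec$provenance <- cal$provenance
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname serialize_calibration
#' @export
parse_calibration <- function(text = NULL, path = NULL) {
  src <- if (!is.null(path)) path else text
  if (is.null(src)) stop("supply `text` or `path`", call. = FALSE)
  rec <- tryCatch(jsonlite::fromJSON(src, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed calibration record: ", conditionMessage(e),
                         call. = FALSE))
  for (f in c("slope", "intercept", "fit_direction", "method")) {
    if (is.null(rec[[f]]))
      stop("calibration record is missing field `", f, "`", call. = FALSE)
  }
  if (!is.numeric(rec$slope) || !is.numeric(rec$intercept))
    stop("calibration record field `slope`/`intercept` must be numeric",
         call. = FALSE)
  calibration_function(rec$slope, rec$intercept, rec$fit_direction,
                       rec$method,
                       units = if (is.null(rec$units)) "mg/cm^3 CaHA" else rec$units,
                       r_squared = rec$r_squared,
                       provenance = rec$provenance)
}
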
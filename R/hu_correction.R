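#' Cross-calibration HU correction
#'
#' An affine map `HU_corrected = gain * HU + offset` that harmonises scans
#' from an aberrant scanner or reconstruction kernel onto the reference
#' scanner on which downstream models were validated. Gains are positive so
#' the correction is invertible and order-preserving.
#'
#' @param gain multiplicative coefficient (> 0).
#' @param offset additive coefficient in HU.
#' @param label scanner or kernel tag the correction belongs to.
#' @return An object of class `hu_correction`.
#' @seealso [hu_correction_preset()] for the shipped scanner coefficients.
#' @export
hu_correction <- function(gain, offset, label = "custom") {
  gain <- as.numeric(gain); offset <- as.numeric(offset)
  if (length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("`gain` must be a positive scalar", call. = FALSE)
  if (length(offset) != 1L || !is.finite(offset))
    stop("`offset` must be a finite scalar (HU)", call. = FALSE)
  structure(list(gain = gain, offset = offset, label = as.character(label)),
            class = "hu_correction")
}

#' @export
print.hu_correction <- function(x, ...) {
  cat(sprintf("<hu_correction> '%s': HU_corrected = %.4g * HU + %.4g\n",
              x$label, x$gain, x$offset))
  invisible(x)
}

#' Named cross-calibration presets
#'
#' Affine HU corrections toward the Philips-1 reference scanner, measured
#' with a tissue-characterisation phantom:
#'
#' * `"philips2"`: `0.998 * HU + 5.48`
#' * `"toshiba"`: `0.98 * HU - 3.32`
#' * `"toshiba_detail"`: `0.97 * HU + 27.54` (Toshiba detail reconstruction
#'   kernel instead of the standard bone kernel)
#' * `"philips1"`, `"ge"`: identity (reference scanner; GE needed no
#'   correction)
#'
#' @param name preset name (see above).
#' @return An [hu_correction()].
#' @examples
#' apply_hu_correction(
#'   ct_volume(array(0L, c(1, 1, 1)), c(1, 1, 1)),
#'   hu_correction_preset("philips2"))$voxels[1]  # 5.48
#' @export
hu_correction_preset <- function(name = c("philips1", "philips2", "ge",
                                          "toshiba", "toshiba_detail")) {
  name <- match.arg(name)
  switch(name,
    philips1       = hu_correction(1, 0, "philips1"),
    ge             = hu_correction(1, 0, "ge"),
    philips2       = hu_correction(0.998, 5.48, "philips2"),
    toshiba        = hu_correction(0.98, -3.32, "toshiba"),
    toshiba_detail = hu_correction(0.97, 27.54, "toshiba_detail"))
}

#' Correction lookup table
#'
#' `default_correction_table()` returns the shipped scanner/kernel
#' correction table; `read_correction_table()` loads one from a JSON file
#' mapping labels to `{gain, offset}` records; `lookup_hu_correction()`
#' resolves a scan's `scanner_id`/`kernel_id` pair against a table,
#' preferring a kernel-specific entry (`"<scanner>:<kernel>"`) over the
#' plain scanner entry, and falling back to the identity.
#'
#' @param path JSON file of `label: {gain, offset}` records.
#' @param table a named list of [hu_correction()] objects.
#' @param scanner_id,kernel_id acquisition tags as stored on a
#'   [ct_volume()].
#' @return A named list of corrections, or a single [hu_correction()].
#' @export
default_correction_table <- function() {
  tab <- list(
    philips1 = hu_correction_preset("philips1"),
    philips2 = hu_correction_preset("philips2"),
    ge = hu_correction_preset("ge"),
    toshiba = hu_correction_preset("toshiba"))
  tab[["toshiba:detail"]] <- hu_correction_preset("toshiba_detail")
  tab
}

#' @rdname default_correction_table
#' @export
read_correction_table <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(rec), function(lab) {
    r <- rec[[lab]]
    if (is.null(r$gain) || is.null(r$offset))
      stop("correction entry `", lab, "` is missing gain/offset",
           call. = FALSE)
    hu_correction(r$gain, r$offset, lab)
  })
  stats::setNames(out, names(rec))
}

#' @rdname default_correction_table
#' @export
lookup_hu_correction <- function(table, scanner_id, kernel_id = "standard") {
  key <- paste0(scanner_id, ":", kernel_id)
  if (!is.null(table[[key]])) return(table[[key]])
  if (!is.null(table[[scanner_id]])) return(table[[scanner_id]])
  hu_correction(1, 0, "identity")
}

#' Apply a cross-calibration HU correction to a volume
#'
#' Maps every voxel through `gain * HU + offset`. Corrected values are kept
#' real-valued (no re-quantisation to integer HU), since they feed directly
#' into calibration fits.
#'
#' @param vol a [ct_volume()].
#' @param corr an [hu_correction()].
#' @return A corrected [ct_volume()].
#' @export
apply_hu_correction <- function(vol, corr) {
  stopifnot(inherits(vol, "ct_volume"), inherits(corr, "hu_correction"))
  out <- vol
  out$voxels <- corr$gain * vol$voxels + corr$offset
  out$kernel_id <- paste0(vol$kernel_id, "|corrected:", corr$label)
  out
}

#' Invert an HU correction
#'
#' @param corr an [hu_correction()].
#' @return The analytic inverse correction, `HU = (HU' - offset) / gain`.
#' @export
invert_hu_correction <- function(corr) {
  stopifnot(inherits(corr, "hu_correction"))
  hu_correction(1 / corr$gain, -corr$offset / corr$gain,
                paste0("inverse:", corr$label))
}
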
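#' Reference tissue densities for the air-fat-muscle calibration
#'
#' CaHA-equivalent "BMD" values assigned to the air, fat and muscle
#' histogram peaks. The shipped defaults (-840, -80, 30 mg/cm^3) were
#' obtained by phantom-calibrating the tissue peaks of a single-scanner
#' reference subgroup, averaging across scans and rounding; see
#' [derive_reference_densities()] to re-derive them from new cohorts.
#'
#' @param air,fat,muscle densities in mg/cm^3 CaHA-equivalent, ordered
#'   `air < fat < muscle`.
#' @return A named numeric vector of class `reference_densities`.
#' @export
reference_densities <- function(air = -840, fat = -80, muscle = 30) {
  if (!(air < fat && fat < muscle))
    stop("reference densities must be ordered air < fat < muscle",
         call. = FALSE)
  structure(c(air = air, fat = fat, muscle = muscle),
            class = "reference_densities")
}

#' Default HU search windows for the tissue peaks
#'
#' The combined leg histogram shows three dominant peaks; these windows
#' separate them before the peak search. Air sits just above the -1024
#' export floor, fat around -100 HU, muscle around +40 HU. Windows are
#' configuration, not physics: shift them when a protocol moves the peaks
#' (e.g. an uncorrected aberrant kernel).
#'
#' @return A list of `c(lo, hi)` HU intervals named `air`, `fat`, `muscle`.
#' @export
tissue_windows <- function() {
  list(air = c(-1024, -900), fat = c(-300, -30), muscle = c(0, 100))
}

#' Tissue-peak record
#'
#' HU locations of the air, fat and muscle histogram peaks of one scan,
#' together with the search windows and ROI they came from.
#'
#' @param air_hu,fat_hu,muscle_hu peak HU, ordered
#'   `air_hu < fat_hu < muscle_hu`.
#' @param windows the search windows used (see [tissue_windows()]).
#' @param roi optionally, the `roi_box` the histogram was built from.
#' @return An object of class `tissue_peaks`.
#' @export
tissue_peaks <- function(air_hu, fat_hu, muscle_hu, windows = NULL,
                         roi = NULL) {
  if (!(air_hu < fat_hu && fat_hu < muscle_hu))
    stop("peaks must be ordered air < fat < muscle (got ",
         paste(c(air_hu, fat_hu, muscle_hu), collapse = ", "), ")",
         call. = FALSE)
  if (!is.null(windows)) {
    for (t in c("air", "fat", "muscle")) {
      p <- switch(t, air = air_hu, fat = fat_hu, muscle = muscle_hu)
      w <- windows[[t]]
      if (!is.null(w) && (p < w[1] || p > w[2]))
        stop(t, " peak ", p, " HU lies outside its search window [",
             w[1], ", ", w[2], "]", call. = FALSE)
    }
  }
  structure(list(air_hu = air_hu, fat_hu = fat_hu, muscle_hu = muscle_hu,
                 windows = windows, roi = roi),
            class = "tissue_peaks")
}

#' @export
print.tissue_peaks <- function(x, ...) {
  cat(sprintf("<tissue_peaks> air %.1f, fat %.1f, muscle %.1f HU\n",
              x$air_hu, x$fat_hu, x$muscle_hu))
  invisible(x)
}

#' Rectangular region of interest
#'
#' In-plane pixel bounds (inclusive on both ends, 1-based) plus the slice
#' indices the ROI spans.
#'
#' @param rows,cols length-2 inclusive index ranges.
#' @param slices slice index vector.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(rows, cols, slices) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  slices <- as.integer(slices)
  if (length(rows) != 2L || length(cols) != 2L || rows[1] > rows[2] ||
      cols[1] > cols[2] || length(slices) == 0L)
    stop("invalid ROI bounds", call. = FALSE)
  structure(list(rows = rows, cols = cols, slices = slices),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows %d:%d, cols %d:%d, %d slice(s)\n",
              x$rows[1], x$rows[2], x$cols[1], x$cols[2], length(x$slices)))
  invisible(x)
}

#' Locate the leg and build the calibration ROI
#'
#' Thresholds the selected slices at `threshold` HU (between air and fat,
#' so any body tissue passes), labels the in-plane connected components of
#' the projected mask, picks the component on the patient-right side (per
#' the volume's display convention), and returns its bounding box expanded
#' by `margin_mm` of surrounding air on each in-plane side — the margin is
#' what brings air into the histogram.
#'
#' @param vol a [ct_volume()].
#' @param slices slice indices to use.
#' @param margin_mm air margin around the leg, in mm (default 10, i.e.
#'   about 1 cm on each side); converted to pixels with `ceiling()`.
#' @param threshold body-tissue threshold in HU.
#' @param min_area_mm2 components smaller than this in-plane area are
#'   treated as speckle (noise, cables, debris) and ignored; any real limb
#'   is orders of magnitude larger than the 100 mm^2 default.
#' @return A [roi_box()].
#' @export
find_leg_roi <- function(vol, slices, margin_mm = 10, threshold = -500,
                         min_area_mm2 = 100) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  slices <- as.integer(slices)
  if (length(slices) == 0L || any(slices < 1L | slices > d[3]))
    stop("`slices` out of range", call. = FALSE)
  proj <- apply(vol$voxels[, , slices, drop = FALSE] > threshold,
                c(1, 2), any)
  if (!any(proj))
    stop("no leg found: no connected tissue above ", threshold, " HU",
         call. = FALSE)
  lab <- EBImage::bwlabel(proj * 1)
  n_comp <- max(lab)
  px_area <- vol$spacing[1] * vol$spacing[2]
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  big <- which(sizes * px_area >= min_area_mm2)
  if (length(big) == 0L)
    stop("no leg found: no tissue component of at least ", min_area_mm2,
         " mm^2", call. = FALSE)
  cent_col <- vapply(big, function(k)
    mean(which(lab == k, arr.ind = TRUE)[, 2]), numeric(1))
  pick <- big[if (vol$patient_side == "radiological") which.min(cent_col)
              else which.max(cent_col)]
  idx <- which(lab == pick, arr.ind = TRUE)
  mr <- ceiling(margin_mm / vol$spacing[1])
  mc <- ceiling(margin_mm / vol$spacing[2])
  roi_box(rows = c(max(1L, min(idx[, 1]) - mr), min(d[1], max(idx[, 1]) + mr)),
          cols = c(max(1L, min(idx[, 2]) - mc), min(d[2], max(idx[, 2]) + mc)),
          slices = slices)
}

#' Combined HU histogram over an ROI
#'
#' Counts voxels per 1-HU bin over all voxels inside the ROI, pooling the
#' listed slices into one histogram. Real-valued (corrected) volumes are
#' binned by rounding to the nearest integer HU. No smoothing is applied.
#'
#' @param vol a [ct_volume()].
#' @param roi a [roi_box()].
#' @return An object of class `hu_histogram`: a list with integer vector
#'   `hu` (bin centers) and `counts`, with `sum(counts)` equal to the ROI
#'   voxel count.
#' @export
build_histogram <- function(vol, roi) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "roi_box"))
  d <- dim(vol$voxels)
  if (roi$rows[2] > d[1] || roi$cols[2] > d[2] || any(roi$slices > d[3]))
    stop("ROI exceeds the image grid", call. = FALSE)
  v <- round(vol$voxels[roi$rows[1]:roi$rows[2],
                        roi$cols[1]:roi$cols[2],
                        roi$slices, drop = FALSE])
  lo <- min(v); hi <- max(v)
  counts <- tabulate(as.vector(v) - lo + 1L, nbins = hi - lo + 1L)
  structure(list(hu = as.integer(lo:hi), counts = counts, roi = roi),
            class = "hu_histogram")
}

#' @export
print.hu_histogram <- function(x, ...) {
  cat(sprintf("<hu_histogram> %d voxels over HU [%d, %d] (1-HU bins)\n",
              sum(x$counts), min(x$hu), max(x$hu)))
  invisible(x)
}

#' Find the tallest histogram bin within a window
#'
#' @param hist an `hu_histogram` from [build_histogram()].
#' @param window `c(lo, hi)` HU interval to search.
#' @return The HU of the maximal-count bin inside the window; ties are
#'   broken toward the lower HU.
#' @export
find_tissue_peak <- function(hist, window) {
  stopifnot(inherits(hist, "hu_histogram"))
  if (length(window) != 2L || window[1] > window[2])
    stop("`window` must be c(lo, hi)", call. = FALSE)
  sel <- hist$hu >= window[1] & hist$hu <= window[2]
  if (!any(sel))
    stop("window [", window[1], ", ", window[2],
         "] does not overlap the histogram support", call. = FALSE)
  hu <- hist$hu[sel]; ct <- hist$counts[sel]
  hu[which.max(ct)]  # which.max returns the first = lowest HU on ties
}

#' Refine a peak to the windowed mode
#'
#' Recomputes the mode of the HU restricted to `peak +/- halfwidth`,
#' making the located peak robust to outliers and to spurious spikes such
#' as the -1024 export floor. With raw 1-HU bins this is the windowed
#' argmax and coincides with [find_tissue_peak()] run on the narrowed
#' window; the refinement changes the answer only when the initial peak
#' came from a smoothed or coarser-binned pass, or sat on a spike flanked
#' by a taller in-window bin.
#'
#' @param hist an `hu_histogram`.
#' @param peak initial peak HU.
#' @param halfwidth half-width of the mode window in HU (default 50).
#' @return The mode HU (lower-HU tie-break).
#' @export
refine_mode <- function(hist, peak, halfwidth = 50) {
  find_tissue_peak(hist, c(peak - halfwidth, peak + halfwidth))
}

#' Fit the air-fat-muscle calibration
#'
#' Least-squares line of the three tissue peak HU on the reference
#' densities. The fit is reported in the `hu_on_bmd` convention
#' (`HU = slope * BMD + intercept`, slope near 1.2 for protocolised
#' scans); [bmd_from_hu()] inverts it when calibrating volumes.
#'
#' @param peaks a [tissue_peaks()] object (or numeric length-3 vector of
#'   air, fat, muscle peak HU).
#' @param refs a [reference_densities()] vector.
#' @return A [calibration_function()] with `method = "afm"` and the R^2 of
#'   the 3-point fit attached.
#' @export
fit_afm_calibration <- function(peaks, refs = reference_densities()) {
  if (is.numeric(peaks) && length(peaks) == 3L)
    peaks <- tissue_peaks(peaks[1], peaks[2], peaks[3])
  stopifnot(inherits(peaks, "tissue_peaks"))
  if (length(refs) != 3L)
    stop("need reference densities for all three tissues", call. = FALSE)
  refs <- reference_densities(refs[["air"]], refs[["fat"]], refs[["muscle"]])
  hu <- c(peaks$air_hu, peaks$fat_hu, peaks$muscle_hu)
  bmd <- as.numeric(refs)
  fit <- stats::lm(hu ~ bmd)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((hu - mean(hu))^2)
  calibration_function(stats::coef(fit)[["bmd"]],
                       stats::coef(fit)[["(Intercept)"]],
                       "hu_on_bmd", "afm", r_squared = r2,
                       provenance = list(peaks_hu = hu,
                                         reference_bmd = bmd))
}

# round to the nearest `to`, halves away from zero (commercial rounding,
# so that e.g. -835 -> -840 rather than banker's -830)
round_to <- function(x, to = 10) to * sign(x) * floor(abs(x) / to + 0.5)

#' Derive reference densities from phantom-calibrated scans
#'
#' Re-derives the air/fat/muscle reference densities for a new scanner or
#' cohort: each scan's tissue peaks are converted to BMD through that
#' scan's own phantom calibration, averaged per tissue across scans, and
#' rounded to the nearest 10 mg/cm^3.
#'
#' @param scans a list where each element is a list with components
#'   `peaks` (a [tissue_peaks()]) and `cal` (that scan's phantom
#'   [calibration_function()]).
#' @return A [reference_densities()] vector; the number of scans used is
#'   attached as attribute `n_scans`.
#' @export
derive_reference_densities <- function(scans) {
  if (!is.list(scans) || length(scans) == 0L)
    stop("`scans` must be a non-empty list", call. = FALSE)
  bmd <- vapply(scans, function(s) {
    stopifnot(inherits(s$peaks, "tissue_peaks"),
              inherits(s$cal, "calibration_function"))
    bmd_from_hu(s$cal, c(s$peaks$air_hu, s$peaks$fat_hu, s$peaks$muscle_hu))
  }, numeric(3))
  avg <- rowMeans(bmd)
  out <- reference_densities(round_to(avg[1], 10), round_to(avg[2], 10),
                             round_to(avg[3], 10))
  attr(out, "n_scans") <- length(scans)
  out
}

# wrap a pipeline stage so errors carry the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' End-to-end air-fat-muscle calibration of a scan
#'
#' The fully automated phantomless pipeline: locate the leg ROI, build the
#' combined 1-HU histogram over the selected slices, find the air, fat and
#' muscle peaks in their search windows, refine each to the mode within
#' +/- `halfwidth` HU, and fit the calibration line against the reference
#' densities. Deterministic: the same volume always yields the same
#' calibration. No scanner- or kernel-specific HU correction is applied —
#' the method recalibrates through the tissues actually in the image,
#' which is what makes it self-correcting under affine protocol changes.
#'
#' @param vol a [ct_volume()].
#' @param slices slice indices (protocol: nine diaphyseal slices).
#' @param refs a [reference_densities()] vector.
#' @param windows tissue search windows, see [tissue_windows()].
#' @param margin_mm air margin for [find_leg_roi()].
#' @param halfwidth mode half-width in HU for [refine_mode()].
#' @param threshold body threshold in HU for [find_leg_roi()].
#' @return A list of class `afm_result` with components `calibration`,
#'   `peaks`, `roi` and `histogram`.
#' @examples
#' scan <- make_scan(scan_recipe(seed = 42))
#' res <- calibrate_afm(scan$volume, slices = 1:9)
#' res$calibration
#' @export
calibrate_afm <- function(vol, slices = 1:9, refs = reference_densities(),
                          windows = tissue_windows(), margin_mm = 10,
                          halfwidth = 50, threshold = -500) {
  stopifnot(inherits(vol, "ct_volume"))
  roi <- with_stage("find_leg_roi",
                    find_leg_roi(vol, slices, margin_mm, threshold))
  hist <- with_stage("build_histogram", build_histogram(vol, roi))
  modes <- vapply(c("air", "fat", "muscle"), function(t) {
    pk <- with_stage(paste0("find_tissue_peak:", t),
                     find_tissue_peak(hist, windows[[t]]))
    with_stage(paste0("refine_mode:", t), refine_mode(hist, pk, halfwidth))
  }, numeric(1))
  peaks <- with_stage("tissue_peaks",
                      tissue_peaks(modes[["air"]], modes[["fat"]],
                                   modes[["muscle"]], windows = windows,
                                   roi = roi))
  cal <- with_stage("fit_afm_calibration", fit_afm_calibration(peaks, refs))
  structure(list(calibration = cal, peaks = peaks, roi = roi,
                 histogram = hist),
            class = "afm_result")
}

#' @export
print.afm_result <- function(x, ...) {
  print(x$calibration)
  print(x$peaks)
  print(x$roi)
  invisible(x)
}
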
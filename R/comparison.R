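#' Nonlinear bone-strength surrogate
#'
#' A scalar endpoint standing downstream of calibration, defined as
#' `S = sum(BMD^gamma) * voxel_volume` over voxels with `BMD >
#' bone_threshold`. It is deliberately nonlinear in BMD (`gamma > 1`), so
#' calibration differences propagate non-proportionally — the same reason
#' a femur's finite-element failure load reacts nonlinearly to calibration
#' changes. It is **not** a failure load and carries arbitrary strength
#' units (mg^gamma cm^(3 - 3 gamma)).
#'
#' @param bmd a [bmd_volume()].
#' @param bone_threshold voxels above this BMD (mg/cm^3) count as bone.
#' @param gamma nonlinearity exponent (> 1); default 2.
#' @return The surrogate scalar; 0 with a warning when no voxel exceeds
#'   the threshold.
#' @export
strength_surrogate <- function(bmd, bone_threshold = 150, gamma = 2) {
  stopifnot(inherits(bmd, "bmd_volume"))
  if (gamma <= 1)
    stop("`gamma` must exceed 1: the surrogate must be nonlinear in BMD",
         call. = FALSE)
  mask <- bmd$voxels > bone_threshold
  if (!any(mask)) {
    warning("empty bone mask: no voxel exceeds ", bone_threshold,
            " mg/cm^3", call. = FALSE)
    return(0)
  }
  voxel_cm3 <- prod(bmd$spacing) / 1000  # mm^3 -> cm^3
  sum(bmd$voxels[mask]^gamma) * voxel_cm3
}

#' Bland-Altman agreement between two methods
#'
#' Differences `d = a - b` per subject, summarised as mean difference, SD
#' of differences (n - 1 denominator) and normal-theory 95% limits of
#' agreement `mean(d) +/- 1.96 * SD(d)`, plus the Pearson correlation of
#' the paired outcomes.
#'
#' @param a,b numeric vectors of the paired outcomes (same units, same
#'   length, >= 2 pairs). Alternatively `a` may be a two-column data
#'   frame.
#' @return An object of class `agreement_summary` with fields
#'   `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `r`, `r_squared`,
#'   `n`. `r` is `NA` when either method has zero variance.
#' @examples
#' bland_altman(c(2, 4, 6), c(1, 2, 3))
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.data.frame(a) && is.null(b)) {
    b <- a[[2]]; a <- a[[1]]
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired outcomes must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need >= 2 pairs for dispersion statistics", call. = FALSE)
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
       else stats::cor(a, b)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 r = r, r_squared = if (is.na(r)) NA_real_ else r^2,
                 n = length(a)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> n = %d, mean diff %.4g (SD %.4g), LoA [%.4g, %.4g]\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  if (is.na(x$r)) cat("  r undefined (zero variance in one method)\n")
  else cat(sprintf("  r = %.4f, R^2 = %.4f\n", x$r, x$r_squared))
  invisible(x)
}

#' Compare calibration methods across a cohort of scans
#'
#' Runs the selected calibration methods on every scan, converts each scan
#' to BMD under each method, computes the strength surrogate, and
#' summarises agreement of each method against the phantom calibration
#' (the gold standard) with Bland-Altman statistics on the surrogate.
#'
#' The phantom calibration is always fitted (it anchors the comparison and
#' supplies the cohort average when no `nps_cal` is given). Scans whose
#' phantom fit or per-method calibration fails are recorded under
#' `failures` and excluded from the summaries.
#'
#' @param scans a list of scans as returned by [make_scan()]: each element
#'   a list with `volume` (a [ct_volume()]) and `truth` carrying
#'   `rod_centers`, `rod_radius` and the recipe's rod densities. For real
#'   data, supply the same structure with a `rods` list
#'   (`centers`, `radius`, `densities`) in place of `truth`.
#' @param methods subset of `c("phantom", "afm", "nps")`.
#' @param config list of options: `slices` (default `1:9`), `refs`,
#'   `windows`, `margin_mm`, `halfwidth`, `threshold` (leg detection),
#'   `bone_threshold`, `gamma` (surrogate), and `nps_cal` (a fixed
#'   [calibration_function()]; default derives the cohort average from
#'   the per-scan phantom calibrations).
#' @return An object of class `method_comparison`: list with `results`
#'   (per scan x method data frame of slope, intercept and surrogate),
#'   `agreement` (named list of [bland_altman()] summaries, method minus
#'   phantom), `calibrations`, `nps_calibration`, and `failures`.
#' @export
compare_methods <- function(scans, methods = c("phantom", "afm", "nps"),
                            config = list()) {
  if (!is.list(scans) || length(scans) == 0L)
    stop("`scans` must be a non-empty list", call. = FALSE)
  methods <- match.arg(methods, c("phantom", "afm", "nps"),
                       several.ok = TRUE)
  cfg <- modifyList(list(slices = 1:9, refs = reference_densities(),
                         windows = tissue_windows(), margin_mm = 10,
                         halfwidth = 50, threshold = -500,
                         bone_threshold = 150, gamma = 2, nps_cal = NULL),
                    config)
  ids <- names(scans)
  if (is.null(ids)) ids <- sprintf("scan%02d", seq_along(scans))

  rods_of <- function(scan) {
    if (!is.null(scan$rods)) return(scan$rods)
    if (!is.null(scan$truth))
      return(list(centers = scan$truth$rod_centers,
                  radius = scan$truth$rod_radius,
                  densities = scan$truth$recipe$rod_densities))
    stop("scan carries neither `rods` geometry nor synthetic `truth`",
         call. = FALSE)
  }

  failures <- list()
  phantom_cals <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    phantom_cals[[i]] <- tryCatch({
      rods <- rods_of(scans[[i]])
      fit_phantom_calibration(
        sample_rods(scans[[i]]$volume, rods$centers, rods$radius,
                    rods$densities, cfg$slices))
    }, error = function(e) {
      failures[[ids[i]]] <<- paste0("phantom: ", conditionMessage(e))
      NULL
    })
  }
  keep <- !vapply(phantom_cals, is.null, logical(1))
  if (!any(keep))
    stop("phantom calibration failed on every scan", call. = FALSE)

  nps_cal <- cfg$nps_cal
  if (is.null(nps_cal) && "nps" %in% methods)
    nps_cal <- derive_nps(phantom_cals[keep])

  rows <- list(); cals <- list()
  surrogate <- matrix(NA_real_, nrow = length(scans), ncol = length(methods),
                      dimnames = list(ids, methods))
  for (i in which(keep)) {
    vol <- scans[[i]]$volume
    for (m in methods) {
      cal <- tryCatch(switch(m,
        phantom = phantom_cals[[i]],
        nps = nps_cal,
        afm = calibrate_afm(vol, cfg$slices, cfg$refs, cfg$windows,
                            cfg$margin_mm, cfg$halfwidth,
                            cfg$threshold)$calibration),
        error = function(e) {
          failures[[paste0(ids[i], ":", m)]] <<- conditionMessage(e)
          NULL
        })
      if (is.null(cal)) next
      s <- strength_surrogate(apply_calibration(vol, cal),
                              cfg$bone_threshold, cfg$gamma)
      surrogate[i, m] <- s
      cals[[paste0(ids[i], ":", m)]] <- cal
      rows[[length(rows) + 1L]] <-
        data.frame(scan = ids[i], method = m, slope = cal$slope,
                   intercept = cal$intercept,
                   fit_direction = cal$fit_direction, strength = s)
    }
  }
  results <- do.call(rbind, rows)
  agreement <- list()
  if ("phantom" %in% methods) {
    for (m in setdiff(methods, "phantom")) {
      ok <- stats::complete.cases(surrogate[, c(m, "phantom"), drop = FALSE])
      if (sum(ok) >= 2L)
        agreement[[paste0(m, "_vs_phantom")]] <-
          bland_altman(surrogate[ok, m], surrogate[ok, "phantom"])
    }
  }
  structure(list(results = results, agreement = agreement,
                 calibrations = cals, nps_calibration = nps_cal,
                 failures = failures),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$results)
  for (nm in names(x$agreement)) {
    cat(nm, ": ")
    print(x$agreement[[nm]])
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (nm in names(x$failures)) cat("  ", nm, ": ", x$failures[[nm]], "\n")
  }
  invisible(x)
}
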
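#' Sample mean HU inside calibration-phantom rods
#'
#' Measures the mean HU inside each rod of a solid calibration phantom over
#' a set of diaphyseal slices. For each rod, every voxel whose in-plane
#' center lies within `rod_radius` of the rod center is pooled across all
#' requested slices before averaging (with axially uniform rods this equals
#' the mean of per-slice means). Nine slices is the protocol default.
#'
#' @param vol a [ct_volume()].
#' @param rod_centers numeric matrix (or data frame) with one `(x, y)` row
#'   per rod, in mm.
#' @param rod_radius rod radius in mm; voxels are selected within this
#'   distance of the center.
#' @param densities nominal CaHA concentrations of the rods (mg/cm^3),
#'   strictly increasing. Defaults to the 0/50/100/200 four-rod phantom.
#' @param slices slice indices to pool; defaults to the first nine.
#' @return A `rod_samples` data frame with columns `rod`, `density`,
#'   `mean_hu`, `n_voxels`, and the slice list as attribute `slices`.
#' @export
sample_rods <- function(vol, rod_centers, rod_radius,
                        densities = c(0, 50, 100, 200), slices = 1:9) {
  stopifnot(inherits(vol, "ct_volume"))
  rod_centers <- as.matrix(rod_centers)
  if (ncol(rod_centers) != 2L)
    stop("`rod_centers` must have one (x, y) row per rod", call. = FALSE)
  n_rods <- nrow(rod_centers)
  if (n_rods < 2L) stop("need >= 2 rods", call. = FALSE)
  if (length(densities) != n_rods)
    stop("`densities` must match the number of rod centers", call. = FALSE)
  if (any(diff(densities) <= 0))
    stop("`densities` must be strictly increasing", call. = FALSE)
  d <- dim(vol$voxels)
  slices <- as.integer(slices)
  if (length(slices) == 0L || any(slices < 1L) || any(slices > d[3]))
    stop("`slices` out of range for a volume with ", d[3], " slices",
         call. = FALSE)
  sp <- vol$spacing
  y <- (seq_len(d[1]) - 0.5) * sp[1]
  x <- (seq_len(d[2]) - 0.5) * sp[2]
  X <- matrix(x, d[1], d[2], byrow = TRUE)
  Y <- matrix(y, d[1], d[2])
  out <- data.frame(rod = seq_len(n_rods), density = densities,
                    mean_hu = NA_real_, n_voxels = NA_integer_)
  for (i in seq_len(n_rods)) {
    m <- (X - rod_centers[i, 1])^2 + (Y - rod_centers[i, 2])^2 <= rod_radius^2
    if (!any(m))
      stop("rod ", i, " mask is empty (center ",
           paste(rod_centers[i, ], collapse = ", "), " mm, radius ",
           rod_radius, " mm)", call. = FALSE)
    vals <- vol$voxels[, , slices, drop = FALSE][array(m, c(d[1:2], length(slices)))]
    out$mean_hu[i] <- mean(vals)
    out$n_voxels[i] <- length(vals)
  }
  attr(out, "slices") <- slices
  attr(out, "rod_radius") <- rod_radius
  class(out) <- c("rod_samples", "data.frame")
  out
}

#' Fit the phantom calibration
#'
#' Ordinary least-squares regression of the nominal rod densities on the
#' sampled mean HU, yielding the gold-standard `BMD = slope * HU +
#' intercept` map for one scan.
#'
#' @param samples a `rod_samples` table from [sample_rods()], or any data
#'   frame with `density` and `mean_hu` columns.
#' @return A [calibration_function()] with `fit_direction = "bmd_on_hu"`,
#'   `method = "phantom"` and the fit R^2 attached.
#' @export
fit_phantom_calibration <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("density", "mean_hu") %in% names(samples)))
    stop("`samples` must have `density` and `mean_hu` columns", call. = FALSE)
  if (nrow(samples) < 2L) stop("need >= 2 rods to fit", call. = FALSE)
  if (length(unique(samples$mean_hu)) < 2L)
    stop("degenerate rod samples: all mean HU identical", call. = FALSE)
  fit <- stats::lm(density ~ mean_hu, data = samples)
  co <- stats::coef(fit)
  # direct R^2 (summary.lm warns on exactly collinear rod sets)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((samples$density - mean(samples$density))^2)
  calibration_function(co[["mean_hu"]], co[["(Intercept)"]],
                       "bmd_on_hu", "phantom", r_squared = r2,
                       provenance = list(n_rods = nrow(samples),
                                         slices = attr(samples, "slices"),
                                         densities = samples$density))
}

#' Average calibration functions into a non-patient-specific map
#'
#' Builds a cohort-level calibration by averaging the slopes and intercepts
#' of per-scan calibration functions (the functions are averaged literally;
#' pooled data are not refit). All inputs must share the `bmd_on_hu`
#' convention and units.
#'
#' @param cals a list of [calibration_function()] objects.
#' @return A [calibration_function()] with `method = "nps"`.
#' @examples
#' derive_nps(list(calibration_function(0.8, -4, "bmd_on_hu", "phantom"),
#'                 calibration_function(0.84, -4.4, "bmd_on_hu", "phantom")))
#' @export
derive_nps <- function(cals) {
  if (!is.list(cals) || length(cals) == 0L)
    stop("`cals` must be a non-empty list of calibration functions",
         call. = FALSE)
  ok <- vapply(cals, inherits, logical(1), "calibration_function")
  if (!all(ok)) stop("all elements must be calibration_function objects",
                     call. = FALSE)
  dirs <- vapply(cals, `[[`, character(1), "fit_direction")
  if (any(dirs != "bmd_on_hu"))
    stop("all calibrations must use fit_direction = 'bmd_on_hu'",
         call. = FALSE)
  un <- unique(vapply(cals, `[[`, character(1), "units"))
  if (length(un) != 1L)
    stop("all calibrations must share the same units", call. = FALSE)
  calibration_function(mean(vapply(cals, `[[`, numeric(1), "slope")),
                       mean(vapply(cals, `[[`, numeric(1), "intercept")),
                       "bmd_on_hu", "nps", units = un,
                       provenance = list(n_functions = length(cals)))
}
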
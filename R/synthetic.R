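#' Geometry of the synthetic leg-on-phantom cross-section
#'
#' All lengths in mm, in-plane coordinates `(x, y)` with `x` along columns
#' and `y` along rows, origin at the image corner. The leg is a set of
#' concentric cylinders (marrow core, cortical shell, muscle, subcutaneous
#' fat) resting above a rod-bearing calibration slab; everything else is
#' air. Setting `second_leg_center` renders a second (left) leg, which is
#' useful for exercising the patient-side selection logic of
#' [find_leg_roi()].
#'
#' @param leg_center,second_leg_center length-2 `(x, y)` centers in mm;
#'   `second_leg_center = NULL` (default) renders a single right leg.
#' @param leg_radius,muscle_radius,cortex_radius,marrow_radius outer radii
#'   of the fat, muscle, cortical and marrow regions (mm).
#' @param slab_x,slab_y in-plane extents of the calibration slab (mm).
#' @param rod_x,rod_y,rod_radius rod center abscissae, common ordinate, and
#'   radius (mm); one rod per entry of `rod_x`.
#' @return A named list used by [scan_recipe()].
#' @export
default_geometry <- function(leg_center = c(55, 66),
                             leg_radius = 38, muscle_radius = 30,
                             cortex_radius = 13, marrow_radius = 8,
                             slab_x = c(12, 168), slab_y = c(112, 150),
                             rod_x = c(50, 80, 110, 140), rod_y = 131,
                             rod_radius = 6,
                             second_leg_center = NULL) {
  rod_y <- rep(rod_y, length.out = length(rod_x))
  g <- list(leg_center = leg_center, leg_radius = leg_radius,
            muscle_radius = muscle_radius, cortex_radius = cortex_radius,
            marrow_radius = marrow_radius, slab_x = slab_x, slab_y = slab_y,
            rod_x = rod_x, rod_y = rod_y, rod_radius = rod_radius,
            second_leg_center = second_leg_center)
  if (!(marrow_radius < cortex_radius && cortex_radius < muscle_radius &&
        muscle_radius < leg_radius))
    stop("leg radii must be strictly nested: marrow < cortex < muscle < fat",
         call. = FALSE)
  if (rod_radius <= 0) stop("rod_radius must be positive", call. = FALSE)
  g
}

#' Recipe for a synthetic leg-on-phantom CT scan
#'
#' Defines the ground-truth scanner mapping `HU = true_gain * density +
#' true_offset`, the tissue and rod densities (CaHA-equivalent mg/cm^3),
#' the cross-section geometry, the noise level and the grid. Defaults
#' emulate a protocolised femoral QCT acquisition: 0.9375 mm in-plane
#' resolution, 3 mm slices, nine diaphyseal slices, and a four-rod solid
#' calibration phantom with 0/50/100/200 mg/cm^3 CaHA rods under the leg.
#'
#' Tissue densities default to the reference values used by the
#' air-fat-muscle calibration (air -840, fat -80, muscle 30) plus marrow 0
#' and cortical bone 1000. The cortex value is a rendering default only and
#' is never used as a calibration reference. The default scanner mapping
#' (gain 1.194, offset 2.232 HU) places the tissue peaks where a
#' protocolised scanner puts them (air near -1000 HU, fat near -93,
#' muscle near 38).
#'
#' @param true_gain,true_offset ground-truth affine density-to-HU mapping
#'   (HU per mg/cm^3, and HU).
#' @param tissue_densities named vector with entries `air`, `fat`,
#'   `muscle`, `marrow`, `cortex` (mg/cm^3 CaHA-equivalent), ordered
#'   `air < fat < marrow <= muscle < cortex`.
#' @param rod_densities strictly increasing CaHA rod concentrations
#'   (mg/cm^3).
#' @param slab_density density of the slab material embedding the rods.
#' @param geometry see [default_geometry()].
#' @param noise_sd additive Gaussian noise SD in HU applied before integer
#'   rounding; 10 HU by default, typical soft-tissue noise for a 3 mm
#'   abdominal-protocol reconstruction.
#' @param n_slices number of axial slices (>= 1; nine matches the
#'   diaphyseal calibration protocol).
#' @param dim_inplane grid size `(rows, cols)`.
#' @param spacing voxel spacing `(row, col, slice)` in mm.
#' @param scanner_id,kernel_id tags copied onto the generated volume.
#' @param seed RNG seed; identical recipes with identical seeds generate
#'   bit-identical volumes.
#' @return An object of class `scan_recipe`.
#' @export
scan_recipe <- function(true_gain = 1.194, true_offset = 2.232,
                        tissue_densities = c(air = -840, fat = -80,
                                             muscle = 30, marrow = 0,
                                             cortex = 1000),
                        rod_densities = c(0, 50, 100, 200),
                        slab_density = 0,
                        geometry = default_geometry(),
                        noise_sd = 10, n_slices = 9L,
                        dim_inplane = c(192L, 192L),
                        spacing = c(0.9375, 0.9375, 3),
                        scanner_id = "sim", kernel_id = "standard",
                        seed = 1L) {
  td <- tissue_densities
  need <- c("air", "fat", "muscle", "marrow", "cortex")
  if (!all(need %in% names(td)))
    stop("tissue_densities must name ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!(td["air"] < td["fat"] && td["fat"] < td["marrow"] &&
        td["marrow"] <= td["muscle"] && td["muscle"] < td["cortex"]))
    stop("tissue densities must be ordered air < fat < marrow <= muscle < cortex",
         call. = FALSE)
  if (length(rod_densities) < 2L || any(diff(rod_densities) <= 0))
    stop("rod_densities must be strictly increasing with >= 2 rods",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (true_gain <= 0) stop("true_gain must be positive", call. = FALSE)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  structure(
    list(true_gain = true_gain, true_offset = true_offset,
         tissue_densities = td[need], rod_densities = rod_densities,
         slab_density = slab_density, geometry = geometry,
         noise_sd = noise_sd, n_slices = as.integer(n_slices),
         dim_inplane = as.integer(dim_inplane), spacing = as.numeric(spacing),
         scanner_id = scanner_id, kernel_id = kernel_id,
         seed = as.integer(seed)),
    class = "scan_recipe")
}

# region label codes used in the ground-truth label volume
.region_codes <- function(n_rods) {
  c(air = 0L, fat = 1L, muscle = 2L, marrow = 3L, cortex = 4L, slab = 5L,
    stats::setNames(5L + seq_len(n_rods), paste0("rod", seq_len(n_rods))))
}

# 2D label matrix for one axial slice of the recipe geometry
.render_labels <- function(recipe) {
  g <- recipe$geometry
  nr <- recipe$dim_inplane[1]; nc <- recipe$dim_inplane[2]
  sp <- recipe$spacing
  y <- ((seq_len(nr)) - 0.5) * sp[1]
  x <- ((seq_len(nc)) - 0.5) * sp[2]
  extent <- c(nr * sp[1], nc * sp[2])  # (y, x) in mm
  inside <- function(cx, cy, r)
    cx - r >= 0 && cx + r <= extent[2] && cy - r >= 0 && cy + r <= extent[1]
  legs <- list(g$leg_center)
  if (!is.null(g$second_leg_center)) legs <- c(legs, list(g$second_leg_center))
  for (lc in legs)
    if (!inside(lc[1], lc[2], g$leg_radius))
      stop("leg geometry does not fit the image grid", call. = FALSE)
  for (i in seq_along(g$rod_x))
    if (!inside(g$rod_x[i], g$rod_y[i], g$rod_radius))
      stop("rod geometry does not fit the image grid", call. = FALSE)
  if (g$slab_x[1] < 0 || g$slab_x[2] > extent[2] ||
      g$slab_y[1] < 0 || g$slab_y[2] > extent[1])
    stop("slab geometry does not fit the image grid", call. = FALSE)
  if (length(g$rod_x) != length(recipe$rod_densities))
    stop("geometry has ", length(g$rod_x), " rods but recipe has ",
         length(recipe$rod_densities), " rod densities", call. = FALSE)

  codes <- .region_codes(length(recipe$rod_densities))
  lab <- matrix(codes[["air"]], nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  lab[X >= g$slab_x[1] & X <= g$slab_x[2] &
      Y >= g$slab_y[1] & Y <= g$slab_y[2]] <- codes[["slab"]]
  for (i in seq_along(g$rod_x)) {
    m <- (X - g$rod_x[i])^2 + (Y - g$rod_y[i])^2 <= g$rod_radius^2
    lab[m] <- codes[[paste0("rod", i)]]
  }
  for (lc in legs) {
    d2 <- (X - lc[1])^2 + (Y - lc[2])^2
    lab[d2 <= g$leg_radius^2] <- codes[["fat"]]
    lab[d2 <= g$muscle_radius^2] <- codes[["muscle"]]
    lab[d2 <= g$cortex_radius^2] <- codes[["cortex"]]
    lab[d2 <= g$marrow_radius^2] <- codes[["marrow"]]
  }
  attr(lab, "codes") <- codes
  lab
}

#' Generate a synthetic CT scan with ground truth
#'
#' Renders the recipe's cross-section, maps each region's density through
#' the ground-truth affine scanner mapping, adds Gaussian noise, rounds to
#' integer HU and clamps to the 12-bit export range `[-1024, 4000]`. The
#' same recipe and seed always produce bit-identical volumes. Integer
#' rounding is applied deliberately (CT exports are integer HU) and bounds
#' the accuracy with which any calibration can recover the mapping.
#'
#' @param recipe a [scan_recipe()].
#' @return A list with components:
#'   \describe{
#'     \item{volume}{the [ct_volume()].}
#'     \item{truth}{a `ground_truth` list: the recipe; the 3D region label
#'       array (`labels`, with a `codes` attribute naming the integer
#'       codes); rod centers in mm (`rod_centers`, one `(x, y)` row per
#'       rod) and `rod_radius`; and `true_calibration`, the exact inverse
#'       of the scanner mapping as a `bmd_on_hu` [calibration_function()].}
#'   }
#' @examples
#' scan <- make_scan(scan_recipe(noise_sd = 0, seed = 1))
#' table(scan$truth$labels[, , 1])[1:3]
#' @export
make_scan <- function(recipe) {
  stopifnot(inherits(recipe, "scan_recipe"))
  lab2d <- .render_labels(recipe)
  codes <- attr(lab2d, "codes")
  dens_by_code <- numeric(length(codes))
  dens_by_code[codes[c("air", "fat", "muscle", "marrow", "cortex")] + 1L] <-
    recipe$tissue_densities[c("air", "fat", "muscle", "marrow", "cortex")]
  dens_by_code[codes[["slab"]] + 1L] <- recipe$slab_density
  for (i in seq_along(recipe$rod_densities))
    dens_by_code[codes[[paste0("rod", i)]] + 1L] <- recipe$rod_densities[i]

  nr <- recipe$dim_inplane[1]; nc <- recipe$dim_inplane[2]
  ns <- recipe$n_slices
  labels <- array(rep(as.vector(lab2d), ns), c(nr, nc, ns))
  hu_clean <- recipe$true_gain * dens_by_code[labels + 1L] + recipe$true_offset
  hu <- if (recipe$noise_sd > 0) {
    withr::with_seed(recipe$seed,
                     hu_clean + stats::rnorm(length(hu_clean),
                                             sd = recipe$noise_sd))
  } else hu_clean
  hu <- round(hu)
  hu <- pmin(pmax(hu, -1024), 4000)
  vol <- ct_volume(array(hu, c(nr, nc, ns)), recipe$spacing,
                   scanner_id = recipe$scanner_id,
                   kernel_id = recipe$kernel_id)
  attr(labels, "codes") <- codes
  truth <- structure(
    list(recipe = recipe, labels = labels,
         rod_centers = cbind(x = recipe$geometry$rod_x,
                             y = recipe$geometry$rod_y),
         rod_radius = recipe$geometry$rod_radius,
         true_calibration = calibration_function(
           1 / recipe$true_gain, -recipe$true_offset / recipe$true_gain,
           "bmd_on_hu", "truth",
           provenance = list(true_gain = recipe$true_gain,
                             true_offset = recipe$true_offset,
                             seed = recipe$seed)),
         seed = recipe$seed),
    class = "ground_truth")
  list(volume = vol, truth = truth)
}

#' Simulate an aberrant reconstruction kernel
#'
#' Perturbs a volume by the analytic inverse of a known cross-calibration
#' correction, optionally followed by in-plane Gaussian smoothing, and
#' re-rounds to integer HU. Applying [apply_hu_correction()] with the
#' forward coefficients then restores the original volume to within
#' rounding. This emulates a scan reconstructed with a non-protocol kernel
#' for which the forward correction has been measured.
#'
#' Values are not re-clamped to the -1024 floor: the perturbed scan stands
#' for the aberrant scanner's own export, whose affine relation to the
#' reference scanner is exactly invertible.
#'
#' @param vol a [ct_volume()].
#' @param corr the forward [hu_correction()] whose inverse is applied.
#' @param blur_sd in-plane Gaussian smoothing SD in mm (0 = none).
#' @return The perturbed [ct_volume()], tagged with the aberrant kernel.
#' @export
perturb_kernel <- function(vol, corr, blur_sd = 0) {
  stopifnot(inherits(vol, "ct_volume"), inherits(corr, "hu_correction"))
  if (blur_sd < 0) stop("blur_sd must be >= 0", call. = FALSE)
  v <- (vol$voxels - corr$offset) / corr$gain
  if (blur_sd > 0) {
    sigma_px <- blur_sd / mean(vol$spacing[1:2])
    for (k in seq_len(dim(v)[3]))
      v[, , k] <- EBImage::gblur(v[, , k], sigma = sigma_px)
  }
  out <- vol
  out$voxels <- round(v)
  out$kernel_id <- paste0("aberrant:", corr$label)
  out
}
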
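test_that("leg ROI is the component bounding box plus the air margin", {
  scan <- make_scan(scan_recipe(seed = 1, noise_sd = 0))
  vol <- scan$volume
  # oracle: bounding box of the leg straight from the label volume
  leg <- attr(scan$truth$labels, "codes")[c("fat", "muscle", "marrow",
                                            "cortex")]
  lab1 <- scan$truth$labels[, , 1]
  in_leg <- which(array(lab1 %in% leg, dim(lab1)), arr.ind = TRUE)
  tight <- c(range(in_leg[, 1]), range(in_leg[, 2]))

  roi0 <- find_leg_roi(vol, 1:9, margin_mm = 0)
  expect_equal(c(roi0$rows, roi0$cols), tight, ignore_attr = TRUE)

  # 10 mm at 0.9375 mm pixels expands by ceiling(10 / 0.9375) = 11 px
  roi <- find_leg_roi(vol, 1:9, margin_mm = 10)
  expect_equal(roi$rows, roi0$rows + c(-11L, 11L))
  expect_equal(roi$cols, roi0$cols + c(-11L, 11L))
  expect_equal(roi$slices, 1:9)
})

test_that("the patient-right leg is selected under either convention", {
  geo <- default_geometry(leg_center = c(50, 60), leg_radius = 30,
                          muscle_radius = 24, cortex_radius = 10,
                          marrow_radius = 6,
                          second_leg_center = c(130, 60))
  scan <- make_scan(scan_recipe(geometry = geo, seed = 2, n_slices = 2))
  roi_r <- find_leg_roi(scan$volume, 1:2)
  expect_lt(mean(roi_r$cols), dim(scan$volume)[2] / 2)
  vol_n <- scan$volume
  vol_n$patient_side <- "neurological"
  roi_l <- find_leg_roi(vol_n, 1:2)
  expect_gt(mean(roi_l$cols), dim(scan$volume)[2] / 2)
})

test_that("an empty threshold mask is a hard error", {
  vol <- uniform_volume(-1000, dims = c(16, 16, 2))
  expect_error(find_leg_roi(vol, 1:2), "no leg found")
})

test_that("the combined histogram counts every ROI voxel once in 1-HU bins", {
  vol <- uniform_volume(-1000, dims = c(10, 10, 3))
  roi <- roi_box(c(1, 10), c(1, 10), 1:3)
  h <- build_histogram(vol, roi)
  expect_equal(h$counts[h$hu == -1000], 300)
  expect_equal(sum(h$counts), 300)

  # two-region ROI: half -1000, half 40
  v <- array(-1000, c(10, 10, 2)); v[6:10, , ] <- 40
  h2 <- build_histogram(ct_volume(v, c(1, 1, 1)), roi_box(c(1, 10), c(1, 10), 1:2))
  expect_equal(h2$counts[h2$hu == -1000], 100)
  expect_equal(h2$counts[h2$hu == 40], 100)
  expect_equal(sum(h2$counts), 200)
})

test_that("peak search is a windowed argmax with a lower-HU tie-break", {
  v <- array(c(rep(-1000, 1e5), rep(-95, 50), rep(-70, 80), rep(30, 60),
               rep(40, 60)), c(1, 1, 100250))
  h <- build_histogram(ct_volume(v, c(1, 1, 1)),
                       roi_box(c(1, 1), c(1, 1), 1:100250))
  expect_equal(find_tissue_peak(h, c(-1024, -900)), -1000)
  expect_equal(find_tissue_peak(h, c(-300, -30)), -70)   # 80 > 50 counts
  expect_equal(find_tissue_peak(h, c(0, 100)), 30)       # tie -> lower HU
  expect_error(find_tissue_peak(h, c(2000, 2100)), "support")
})

test_that("mode refinement escapes spikes flanked by taller in-window bins", {
  # air floor spike at -1024, true tissue bin slightly taller at -1000
  v <- array(c(rep(-1024, 500), rep(-1000, 600), rep(30, 50)),
             c(1, 1, 1150))
  h <- build_histogram(ct_volume(v, c(1, 1, 1)),
                       roi_box(c(1, 1), c(1, 1), 1:1150))
  expect_equal(refine_mode(h, -1024), -1000)
  # symmetric unimodal peak is a fixed point
  v2 <- array(rep(c(29, 30, 30, 30, 31), 20), c(1, 1, 100))
  h2 <- build_histogram(ct_volume(v2, c(1, 1, 1)),
                        roi_box(c(1, 1), c(1, 1), 1:100))
  expect_equal(refine_mode(h2, 30), 30)
  # bins beyond the halfwidth are invisible to the refinement
  expect_equal(refine_mode(h, 30, halfwidth = 10), 30)
})

test_that("the 3-point AFM fit matches closed-form least squares", {
  refs <- reference_densities()
  cal <- fit_afm_calibration(c(-1000.7, -93.3, 38.1), refs)
  oracle <- ls_line(as.numeric(refs), c(-1000.7, -93.3, 38.1))
  expect_equal(cal$slope, oracle[["slope"]], tolerance = 1e-12)
  expect_equal(cal$intercept, oracle[["intercept"]], tolerance = 1e-12)
  # consistency with the reported cohort fit statistics
  expect_equal(cal$slope, 1.194, tolerance = 0.016 / 1.194)
  expect_lt(abs(cal$intercept), 2.232 + 12.042)
  expect_gt(cal$r_squared, 0.9999)
  expect_equal(cal$fit_direction, "hu_on_bmd")

  ident <- fit_afm_calibration(c(-840, -80, 30), refs)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-9)
})

test_that("tissue peak records enforce ordering and window membership", {
  expect_error(tissue_peaks(-80, -840, 30), "ordered")
  expect_error(tissue_peaks(-1050, -93, 38, windows = tissue_windows()),
               "outside its search window")
})

test_that("reference derivation averages calibrated peaks, rounded to 10", {
  ident <- calibration_function(1, 0, "bmd_on_hu", "phantom")
  one <- derive_reference_densities(list(
    list(peaks = tissue_peaks(-840, -80, 30), cal = ident)))
  expect_equal(as.numeric(one), c(-840, -80, 30))

  # two scans averaging to (-838.6, -77.9, 31.2) -> (-840, -80, 30)
  two <- derive_reference_densities(list(
    list(peaks = tissue_peaks(-838.6, -77.9, 31.2), cal = ident),
    list(peaks = tissue_peaks(-838.6, -77.9, 31.2), cal = ident)))
  expect_equal(as.numeric(two), c(-840, -80, 30))
  expect_equal(attr(two, "n_scans"), 2)

  # halves round away from zero
  half <- derive_reference_densities(list(
    list(peaks = tissue_peaks(-845, -75, 35), cal = ident)))
  expect_equal(as.numeric(half), c(-850, -80, 40))

  expect_error(derive_reference_densities(list()), "non-empty")
})

test_that("end-to-end AFM calibration is deterministic and recovers truth", {
  scan <- make_scan(scan_recipe(seed = 13, noise_sd = 0))
  a <- calibrate_afm(scan$volume, 1:9)
  b <- calibrate_afm(scan$volume, 1:9)
  expect_identical(a$calibration$slope, b$calibration$slope)
  expect_identical(a$calibration$intercept, b$calibration$intercept)
  # noiseless parameter recovery within 1 mg/cm^3 across the soft-tissue
  # and trabecular range
  expect_lt(recovery_error(a$calibration, scan$truth$true_calibration,
                           c(-1024, 200)), 1)
})

test_that("AFM recalibrates through an uncorrected kernel change", {
  scan <- make_scan(scan_recipe(seed = 14, noise_sd = 0))
  corr <- hu_correction(1.03, -30, "synthetic-kernel")
  pert <- perturb_kernel(scan$volume, corr)  # no forward correction applied
  res <- calibrate_afm(pert, 1:9)
  # truth for the perturbed scan: compose the scanner mapping with the
  # perturbation, i.e. BMD at HU h is truth(corr(h))
  refs <- reference_densities()
  true_cal <- scan$truth$true_calibration
  hu_pert <- (hu_from_bmd(true_cal, as.numeric(refs)) - corr$offset) /
    corr$gain
  rec <- bmd_from_hu(res$calibration, hu_pert)
  expect_lt(max(abs(rec - as.numeric(refs))), 5)
})

test_that("tissue modes shrug off 1% outlier voxels", {
  scan <- make_scan(scan_recipe(seed = 15))
  base <- calibrate_afm(scan$volume, 1:9)
  roi <- base$roi
  vol <- scan$volume
  idx <- which(array(TRUE, dim(vol$voxels)), arr.ind = TRUE)
  in_roi <- idx[, 1] >= roi$rows[1] & idx[, 1] <= roi$rows[2] &
    idx[, 2] >= roi$cols[1] & idx[, 2] <= roi$cols[2]
  roi_lin <- which(in_roi)
  # corrupt voxels that are not themselves inside any +/-50 HU mode
  # window (cortex, slab, rods, region boundaries): outliers entering the
  # ROI leave every windowed mode untouched
  pk <- c(base$peaks$air_hu, base$peaks$fat_hu, base$peaks$muscle_hu)
  v <- vol$voxels[roi_lin]
  eligible <- roi_lin[apply(abs(outer(v, pk, "-")) > 50, 1, all)]
  withr::with_seed(99, {
    hit <- sample(eligible, length(roi_lin) %/% 100)
  })
  vol$voxels[hit] <- 500  # far outside every +/-50 HU mode window
  contaminated <- calibrate_afm(vol, 1:9)
  expect_identical(contaminated$peaks$air_hu, base$peaks$air_hu)
  expect_identical(contaminated$peaks$fat_hu, base$peaks$fat_hu)
  expect_identical(contaminated$peaks$muscle_hu, base$peaks$muscle_hu)
})

test_that("a uniform HU shift moves peaks and intercept, not the slope", {
  scan <- make_scan(scan_recipe(seed = 16))
  base <- calibrate_afm(scan$volume, 1:9)
  shift <- 25
  vol <- scan$volume
  vol$voxels <- vol$voxels + shift
  shifted <- calibrate_afm(vol, 1:9)
  expect_equal(shifted$peaks$air_hu, base$peaks$air_hu + shift)
  expect_equal(shifted$peaks$fat_hu, base$peaks$fat_hu + shift)
  expect_equal(shifted$peaks$muscle_hu, base$peaks$muscle_hu + shift)
  expect_equal(shifted$calibration$slope, base$calibration$slope,
               tolerance = 1e-12)
  expect_equal(shifted$calibration$intercept,
               base$calibration$intercept + shift, tolerance = 1e-9)
})

test_that("AFM self-corrects exactly (to rounding) under affine changes", {
  # any invertible affine perturbation of a noiseless scan: recovered BMD
  # at the three tissue densities is exact up to integer rounding
  refs <- reference_densities()
  for (k in 1:5) {
    # perturbation range chosen so the shifted peaks stay inside the
    # default search windows; larger shifts need re-windowing (config)
    withr::with_seed(100 + k, {
      gain <- runif(1, 1.01, 1.08)
      offset <- runif(1, -10, 10)
    })
    scan <- make_scan(scan_recipe(seed = k, noise_sd = 0))
    pert <- perturb_kernel(scan$volume, hu_correction(gain, offset))
    res <- calibrate_afm(pert, 1:9)
    true_cal <- scan$truth$true_calibration
    hu_tissue <- (hu_from_bmd(true_cal, as.numeric(refs)) - offset) / gain
    err <- abs(bmd_from_hu(res$calibration, hu_tissue) - as.numeric(refs))
    # generation and perturbation each round to integer HU, so a peak can
    # be off by up to ~1 HU; through the ~1.1 HU-per-BMD effective slope
    # that bounds the error at the fit's nodes well under 1.5 mg/cm^3
    expect_lt(max(err), 1.5)
  }
})

test_that("pipeline errors carry their stage name", {
  vol <- uniform_volume(-1000, dims = c(16, 16, 2))
  expect_error(calibrate_afm(vol, 1:2), "find_leg_roi")
})
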
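test_that("apply_calibration honours both fit conventions", {
  v0 <- uniform_volume(0)
  out <- apply_calibration(v0, nps_preset())
  expect_equal(out$voxels[1, 1, 1], -4.2)
  expect_equal(dim(out$voxels), dim(v0$voxels))
  expect_equal(out$spacing, v0$spacing)

  vx <- uniform_volume(137)
  ident <- calibration_function(1, 0, "bmd_on_hu", "phantom")
  expect_equal(apply_calibration(vx, ident)$voxels, vx$voxels)

  # hu_on_bmd is evaluated through the numerical inverse of the affine map
  afm <- calibration_function(1.194, 2.232, "hu_on_bmd", "afm")
  expect_equal(bmd_from_hu(afm, -1000.7), (-1000.7 - 2.232) / 1.194)
  expect_equal(bmd_from_hu(afm, -1000.7), -839.9765, tolerance = 1e-6)
})

test_that("calibration evaluation round-trips through its inverse", {
  cals <- list(calibration_function(0.82, -4.2, "bmd_on_hu", "nps"),
               calibration_function(1.194, 2.232, "hu_on_bmd", "afm"),
               calibration_function(0.63, 17, "bmd_on_hu", "phantom"))
  hu <- seq(-1024, 1600, length.out = 101)
  for (cal in cals)
    expect_equal(hu_from_bmd(cal, bmd_from_hu(cal, hu)), hu,
                 tolerance = 1e-9)
})

test_that("calibration_function rejects degenerate or decreasing maps", {
  expect_error(calibration_function(0, 1, "bmd_on_hu", "phantom"),
               "non-zero")
  expect_error(calibration_function(-0.5, 1, "bmd_on_hu", "phantom"),
               "increasing")
})

test_that("shipped HU corrections embody the measured cross-calibrations", {
  v0 <- uniform_volume(0)
  expect_equal(
    apply_hu_correction(v0, hu_correction_preset("philips2"))$voxels[1],
    5.48)
  expect_equal(
    apply_hu_correction(v0, hu_correction_preset("toshiba_detail"))$voxels[1],
    27.54)
  expect_equal(
    apply_hu_correction(v0, hu_correction_preset("toshiba"))$voxels[1],
    -3.32)
  # reference scanner and GE are identities
  v <- uniform_volume(123)
  for (nm in c("philips1", "ge"))
    expect_equal(apply_hu_correction(v, hu_correction_preset(nm))$voxels,
                 v$voxels)
})

test_that("HU corrections are order-preserving and analytically invertible", {
  corr <- hu_correction_preset("toshiba_detail")
  hu <- sort(runif(50, -1024, 1600))
  vol <- ct_volume(array(hu, c(50, 1, 1)), c(1, 1, 1))
  corrected <- apply_hu_correction(vol, corr)$voxels
  expect_true(all(diff(as.vector(corrected)) > 0))
  back <- apply_hu_correction(ct_volume(corrected, c(1, 1, 1)),
                              invert_hu_correction(corr))$voxels
  expect_equal(as.vector(back), hu, tolerance = 1e-9)
  expect_error(hu_correction(0, 5), "positive")
})

test_that("correction lookup prefers kernel-specific entries", {
  tab <- default_correction_table()
  expect_equal(lookup_hu_correction(tab, "toshiba", "detail")$offset, 27.54)
  expect_equal(lookup_hu_correction(tab, "toshiba", "standard")$offset, -3.32)
  ident <- lookup_hu_correction(tab, "siemens")
  expect_equal(c(ident$gain, ident$offset), c(1, 0))
})

test_that("calibration JSON serialization round-trips losslessly", {
  for (cal in list(nps_preset(),
                   calibration_function(1.194, 2.232, "hu_on_bmd", "afm",
                                        r_squared = 0.99999))) {
    txt <- serialize_calibration(cal)
    back <- parse_calibration(txt)
    expect_equal(back$slope, cal$slope)
    expect_equal(back$intercept, cal$intercept)
    expect_equal(back$fit_direction, cal$fit_direction)
    expect_equal(back$method, cal$method)
    expect_equal(back$units, cal$units)
  }
  expect_error(parse_calibration('{"intercept": -4.2, "fit_direction":
    "bmd_on_hu", "method": "nps"}'), "slope")
})

test_that("NIfTI write/read round-trips voxels and spacing", {
  scan <- make_scan(scan_recipe(seed = 3, n_slices = 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(scan$volume, path)
  back <- read_volume(path)
  expect_equal(back$voxels, scan$volume$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing, scan$volume$spacing)

  # constant single-slice volume; NIfTI drops the singleton axis, so the
  # slice spacing comes back through the fallback argument
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ct_volume(array(100, c(8, 8, 1)), c(1, 1, 3)), p2)
  expect_error(read_volume(p2), "slice spacing")
  v2 <- read_volume(p2, slice_spacing = 3)
  expect_true(all(v2$voxels == 100))
  expect_equal(dim(v2$voxels), c(8L, 8L, 1L))
})

test_that("DICOM series reading applies rescale and checks slice order", {
  dir <- withr::local_tempdir()
  px <- matrix(1024L, 6, 8)  # stored value; HU = 1 * 1024 - 1024 = 0
  px[2, 3] <- 1224L          # one voxel at 200 HU, breaks symmetry
  for (k in 1:3)
    write_test_dicom(file.path(dir, sprintf("s%d.dcm", k)), px,
                     slope = 1, intercept = -1024, z = (k - 1) * 3,
                     instance = k)
  vol <- read_volume(dir, format = "dicom_dir")
  expect_equal(dim(vol$voxels), c(6L, 8L, 3L))
  expect_equal(vol$voxels[1, 1, 1], 0)
  expect_equal(vol$voxels[2, 3, 2], 200)
  expect_equal(vol$spacing, c(0.9375, 0.9375, 3))

  # duplicate slice position -> non-monotone -> hard error
  write_test_dicom(file.path(dir, "s4.dcm"), px, z = 3, instance = 4)
  expect_error(read_volume(dir, format = "dicom_dir"), "monotone")
})

test_that("ct_volume validates spacing and content", {
  expect_error(ct_volume(array(0, c(2, 2, 1)), c(1, -1, 3)), "positive")
  expect_error(ct_volume(array(numeric(0), c(0, 2, 1)), c(1, 1, 3)),
               "non-empty")
  expect_error(ct_volume(matrix(0, 2, 2), c(1, 1, 3)), "3D")
})
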
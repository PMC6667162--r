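# Shared fixtures built in code.

# closed-form least squares of y on x (independent oracle for the lm-based
# calibration fits)
ls_line <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# max |BMD_cal(HU) - BMD_true(HU)| over an HU grid
recovery_error <- function(cal, truth_cal, hu_range, by = 1) {
  grid <- seq(hu_range[1], hu_range[2], by = by)
  max(abs(bmd_from_hu(cal, grid) - bmd_from_hu(truth_cal, grid)))
}

# a bare uniform ct_volume for unit tests that need no anatomy
uniform_volume <- function(hu, dims = c(4, 4, 2), spacing = c(1, 1, 3)) {
  ct_volume(array(hu, dims), spacing)
}
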
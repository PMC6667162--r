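# Write a minimal single-frame DICOM file (implicit VR little endian,
# 16-bit signed pixels) for reader tests. Fixtures are generated at test
# time; nothing binary ships with the package.
write_test_dicom <- function(path, pixels, slope = 1, intercept = -1024,
                             pixel_spacing = c(0.9375, 0.9375),
                             slice_thickness = 3, z = 0, instance = 1) {
  pixels <- as.matrix(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  raw16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
  raw32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))  # even length
    r
  }
  elem <- function(group, element, value) {
    writeBin(c(raw16(group), raw16(element), raw32(length(value)), value),
             con)
  }
  elem(0x0018, 0x0050, str_raw(format(slice_thickness)))
  elem(0x0020, 0x0013, str_raw(format(instance)))
  elem(0x0020, 0x0032, str_raw(sprintf("0\\0\\%s", format(z))))
  elem(0x0028, 0x0010, raw16(nrow(pixels)))
  elem(0x0028, 0x0011, raw16(ncol(pixels)))
  elem(0x0028, 0x0030, str_raw(sprintf("%s\\%s", format(pixel_spacing[1]),
                                       format(pixel_spacing[2]))))
  elem(0x0028, 0x0100, raw16(16))
  elem(0x0028, 0x0103, raw16(1))
  elem(0x0028, 0x1052, str_raw(format(intercept)))
  elem(0x0028, 0x1053, str_raw(format(slope)))
  elem(0x7fe0, 0x0010, raw16(as.vector(t(pixels))))  # row-major
  invisible(path)
}
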
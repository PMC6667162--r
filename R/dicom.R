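# Minimal DICOM series reader.
#
# Supports what CT densitometry exports actually use: single-frame
# uncompressed images in implicit or explicit VR little endian, 16-bit
# pixels, with rescale slope/intercept. Compressed transfer syntaxes,
# big-endian files and undefined-length sequences are rejected.

dcm_uint16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))

dcm_uint32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

dcm_tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

# VRs carrying a 2-byte reserved field + 4-byte length in explicit VR
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one DICOM file, returning the raw values of the tags we need.
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  explicit_meta <- FALSE
  if (length(raw) > 132L && identical(raw[129:132], charToRaw("DICM"))) {
    pos <- 133L
    explicit_meta <- TRUE  # file meta group is always explicit VR
  }
  # sniff main data set VR convention from the first element at `pos`
  sniff_explicit <- function(p) {
    vr <- tryCatch(rawToChar(raw[(p + 4L):(p + 5L)]), error = function(e) "")
    grepl("^[A-Z]{2}$", vr)
  }
  wanted <- c("0008,0060", "0018,0050", "0020,0013", "0020,0032", "0020,1041",
              "0028,0010", "0028,0011", "0028,0030", "0028,0100", "0028,0103",
              "0028,1052", "0028,1053", "7fe0,0010")
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_uint16(raw[pos:(pos + 1L)])
    element <- dcm_uint16(raw[(pos + 2L):(pos + 3L)])
    in_meta <- group == 2L
    explicit <- if (in_meta) explicit_meta else sniff_explicit(pos)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_uint32(raw[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- dcm_uint16(raw[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_uint32(raw[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("DICOM element with undefined length is not supported: ", path,
           call. = FALSE)
    key <- dcm_tag_key(group, element)
    val_start <- pos + hdr
    if (key %in% wanted && len > 0)
      out[[key]] <- raw[val_start:(val_start + len - 1L)]
    pos <- val_start + len
    if (key == "7fe0,0010") break
  }
  out
}

dcm_str <- function(x) if (is.null(x)) NULL else trimws(rawToChar(x))

dcm_ds <- function(x) {
  if (is.null(x)) return(NULL)
  as.numeric(strsplit(dcm_str(x), "\\\\")[[1]])
}

dcm_us <- function(x) if (is.null(x)) NULL else dcm_uint16(x[1:2])

dcm_slice <- function(path) {
  tags <- dcm_parse_file(path)
  rows <- dcm_us(tags[["0028,0010"]])
  cols <- dcm_us(tags[["0028,0011"]])
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
    stop("DICOM file lacks image data: ", path, call. = FALSE)
  bits <- dcm_us(tags[["0028,0100"]])
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit DICOM pixel data is supported (got ", bits, " bits): ",
         path, call. = FALSE)
  signed <- identical(dcm_us(tags[["0028,0103"]]), 1L)
  px <- readBin(tags[["7fe0,0010"]], "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  if (!signed) px[px < 0] <- px[px < 0] + 65536L  # readBin caveat guard
  slope <- dcm_ds(tags[["0028,1053"]]); slope <- if (is.null(slope)) 1 else slope
  inter <- dcm_ds(tags[["0028,1052"]]); inter <- if (is.null(inter)) 0 else inter
  hu <- matrix(px, nrow = cols, ncol = rows)  # stored row-major
  hu <- t(hu) * slope + inter
  pxsp <- dcm_ds(tags[["0028,0030"]])
  ipp <- dcm_ds(tags[["0020,0032"]])
  list(hu = hu,
       pixel_spacing = pxsp,
       z = if (!is.null(ipp)) ipp[3] else dcm_ds(tags[["0020,1041"]]),
       instance = dcm_ds(tags[["0020,0013"]]),
       slice_thickness = dcm_ds(tags[["0018,0050"]]))
}

# Read a directory of single-frame DICOM files as one ct_volume.
read_dicom_series <- function(dir, scanner_id = "unknown",
                              kernel_id = "standard") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, dcm_slice)
  dims <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("DICOM slices have inconsistent dimensions", call. = FALSE)
  z <- vapply(slices, function(s) {
    if (is.null(s$z)) NA_real_ else s$z
  }, numeric(1))
  if (anyNA(z)) {
    inst <- vapply(slices, function(s)
      if (is.null(s$instance)) NA_real_ else s$instance, numeric(1))
    if (anyNA(inst))
      stop("DICOM slices lack position and instance ordering metadata",
           call. = FALSE)
    ord <- order(inst)
    z <- inst
  } else ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1L && any(diff(z) <= 0))
    stop("DICOM slice positions are not strictly monotone", call. = FALSE)
  pxsp <- slices[[1]]$pixel_spacing
  if (is.null(pxsp) || length(pxsp) != 2L || any(pxsp <= 0))
    stop("DICOM pixel spacing metadata is missing", call. = FALSE)
  dz <- if (length(z) > 1L) diff(z)[1] else slices[[1]]$slice_thickness
  if (is.null(dz) || !is.finite(dz) || dz <= 0)
    stop("DICOM slice spacing metadata is missing", call. = FALSE)
  vox <- array(0, c(dim(slices[[1]]$hu), length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  ct_volume(vox, c(pxsp[1], pxsp[2], dz),
            scanner_id = scanner_id, kernel_id = kernel_id)
}
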
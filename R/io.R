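#' Read a CT volume from disk
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a directory containing an
#' uncompressed single-frame DICOM series. Voxels are returned in Hounsfield
#' units: for DICOM the rescale slope/intercept are applied during reading;
#' NIfTI volumes are assumed to store HU already. Voxel spacing is taken
#' from the file metadata and is mandatory.
#'
#' @param path a NIfTI file or a DICOM series directory.
#' @param format `"auto"` (directory = DICOM, file = NIfTI), `"nifti"` or
#'   `"dicom_dir"`.
#' @param scanner_id,kernel_id acquisition tags attached to the volume.
#' @param slice_spacing fallback through-plane spacing in mm, used only
#'   for 2D NIfTI files (single-slice exports whose headers carry no third
#'   pixdim); without it a 2D file is an error.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir"),
                        scanner_id = "unknown", kernel_id = "standard",
                        slice_spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "dicom_dir")
    return(read_dicom_series(path, scanner_id = scanner_id,
                             kernel_id = kernel_id))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  sp <- RNifti::pixdim(img)
  if (length(dim(arr)) == 2L) {
    # single-slice export: the third pixdim is gone with the third axis
    if (is.null(slice_spacing))
      stop("NIfTI volume is 2D and no `slice_spacing` fallback was given; ",
           "slice spacing metadata is missing", call. = FALSE)
    arr <- array(arr, c(dim(arr), 1L))
    sp <- c(sp[1:2], slice_spacing)
  }
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("NIfTI voxel spacing metadata is missing or invalid", call. = FALSE)
  ct_volume(arr, sp[1:3], scanner_id = scanner_id, kernel_id = kernel_id)
}

#' Write a volume as NIfTI
#'
#' Writes a [ct_volume()] or [bmd_volume()] to `.nii` / `.nii.gz`, carrying
#' the voxel spacing in the NIfTI header.
#'
#' @param vol a `ct_volume` or `bmd_volume`.
#' @param path output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("ct_volume", "bmd_volume")))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
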
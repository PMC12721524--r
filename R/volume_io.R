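#' Volume helpers and NIfTI input/output
#'
#' Volumes are plain 3D numeric arrays; voxel spacing (mm) travels in the
#' `"pixdim"` attribute and is written into the NIfTI header. Label volumes
#' and masks are integer-valued arrays on the same grid.
#'
#' @name volume-io
NULL

#' Assert that two volumes share one grid
#'
#' @param a,b 3D arrays.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @keywords internal
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid mismatch: %s have dims %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean intensity within a mask
#'
#' @param volume 3D numeric array.
#' @param mask 3D array; voxels with nonzero values are inside the mask.
#' @return Scalar mean of the within-mask voxel intensities.
#' @export
masked_mean <- function(volume, mask) {
  check_same_grid(volume, mask, "volume and mask")
  idx <- mask != 0
  if (!any(idx)) stop("mask is empty", call. = FALSE)
  mean(volume[idx])
}

#' Write a volume to a NIfTI-1 file
#'
#' Channels are stored as float64 so that a write/read round trip is
#' bit-exact; labels and masks as int16.
#'
#' @param volume 3D array (numeric or integer).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param pixdim voxel spacing in mm, length 3.
#' @param datatype NIfTI storage type, `"double"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, pixdim = attr(volume, "pixdim"),
                         datatype = "double") {
  if (is.null(pixdim)) pixdim <- c(1, 1, 1)
  img <- RNifti::asNifti(array(as.vector(volume), dim = dim(volume)),
                         pixdim = pixdim)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path NIfTI file.
#' @return Plain 3D array with a `"pixdim"` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Otsu-threshold brain mask (fallback only)
#'
#' A convenience foreground mask for volumes that arrive without one, using
#' Otsu's histogram threshold (via EBImage). This is a crude
#' intensity-threshold mask and is not equivalent to a dedicated brain
#' extraction tool; phantom cases carry ground-truth masks and should use
#' those.
#'
#' @param volume 3D numeric array.
#' @return Integer 0/1 array of the same dimensions.
#' @export
brain_mask_from_otsu <- function(volume) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("brain_mask_from_otsu() requires the EBImage package", call. = FALSE)
  }
  rng <- range(volume)
  if (diff(rng) <= 0) stop("constant volume: no threshold exists", call. = FALSE)
  scaled <- (volume - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled, dim = dim(volume)), levels = 256)
  out <- array(as.integer(scaled > thr), dim = dim(volume))
  attr(out, "pixdim") <- attr(volume, "pixdim")
  out
}
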
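#' CT volume and exclusion-mask containers
#'
#' A `ct_volume` is a 3D integer grid of Hounsfield units (HU) plus voxel
#' spacing in centimetres; `exclusion_masks` is an integer label grid of
#' identical geometry marking regions that must not enter tissue
#' measurements. Label semantics: 0 keep, 1 external objects / CT table,
#' 2 non-aerated lung, 3 gastrointestinal or bladder contents, 4 dense
#' non-skeletal objects (implants, microchips, mineralization, calculi).
#'
#' @param hu 3D array of HU values (integer; air is -1024).
#' @param spacing numeric length-3: pixel width, pixel length, slice
#'   thickness, all in cm. The slice thickness must be the effective slice
#'   spacing of the reconstruction (for non-overlapping reconstructions the
#'   two coincide).
#' @param cat_id identifier carried into downstream tables.
#' @param labels 3D integer array of region labels, same dimensions as `hu`.
#'
#' @return `ct_volume()` an object of class `ct_volume`; `exclusion_masks()`
#'   an object of class `exclusion_masks`.
#' @export
ct_volume <- function(hu, spacing, cat_id = "cat") {
  if (length(dim(hu)) != 3L) abort("`hu` must be a 3D array.")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel dimensions in cm.")
  }
  if (any(hu < -1024, na.rm = TRUE)) {
    abort("HU values below -1024 are not valid CT attenuation values.")
  }
  storage.mode(hu) <- "integer"
  structure(
    list(hu = hu, spacing = as.numeric(spacing), cat_id = as.character(cat_id)),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @export
exclusion_masks <- function(labels) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "exclusion_masks")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf(
    "<ct_volume> %s: %d x %d x %d voxels, spacing %.3f x %.3f x %.3f cm, HU range [%d, %d]\n",
    x$cat_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$hu), max(x$hu)
  ))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' The product of pixel width, pixel length, and slice thickness.
#'
#' @param spacing numeric length-3 voxel dimensions in cm.
#' @return Voxel volume in cm^3.
#' @export
voxel_volume <- function(spacing) {
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  prod(spacing)
}

#' Read and write CT volumes and masks as NIfTI
#'
#' Volumes are stored as NIfTI-1 with voxel spacing in the header in mm
#' (the NIfTI convention); spacing is converted to/from the cm used
#' throughout this package. Masks are integer label images of identical
#' geometry.
#'
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @param volume a [ct_volume()].
#' @param masks an [exclusion_masks()].
#' @param cat_id identifier to attach on read.
#' @return `read_ct_volume()` a `ct_volume`; `read_masks()` an
#'   `exclusion_masks`; the writers return `path` invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  img <- RNifti::asNifti(
    volume$hu,
    reference = list(pixdim = c(-1, volume$spacing * 10, 0, 0, 0, 0)),
    datatype = "int16"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path, cat_id = "cat") {
  img <- RNifti::readNifti(path)
  spacing_mm <- RNifti::pixdim(img)[seq_len(3)]
  hu <- array(round_half_away(as.vector(img)), dim = dim(img))
  ct_volume(hu, spacing_mm / 10, cat_id = cat_id)
}

#' @rdname write_ct_volume
#' @export
write_masks <- function(masks, path) {
  RNifti::writeNifti(RNifti::asNifti(masks$labels, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_masks <- function(path) {
  img <- RNifti::readNifti(path)
  exclusion_masks(array(as.integer(img), dim = dim(img)))
}
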
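#' CT volume and region mask containers
#'
#' A `ct_volume` is a 3-D array of attenuation values in Hounsfield units
#' (HU) together with the voxel spacing in mm, so that all downstream
#' measurements (areas in mm^2, volumes in L) are unit-aware.  A
#' `region_mask` is a logical array of identical shape labelling a region of
#' a volume (lung fields, airway lumen, analysis region, ...).
#'
#' Voxel indices are 1-based `(x, y, z)` array indices with `z` the slice
#' axis; the physical centre of voxel `(i, j, k)` is at
#' `origin + (c(i, j, k) - 0.5) * spacing` mm.
#'
#' @param values 3-D numeric array of HU values (finite).
#' @param spacing voxel spacing in mm, length 1 or 3, all positive.
#' @param origin physical position of the corner of voxel (1,1,1), mm.
#' @return `ct_volume()` returns an object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(-1000, c(4, 4, 4)), spacing = 1)
#' voxel_volume_ml(vol)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3-D array")
  if (any(!is.finite(values))) stopf("HU values must all be finite")
  spacing <- rep3(spacing, "spacing")
  if (any(spacing <= 0)) stopf("voxel spacing must be positive on all axes")
  structure(
    list(values = values * 1.0, spacing = spacing, origin = rep3(origin, "origin")),
    class = "ct_volume")
}

#' @rdname ct_volume
#' @param mask logical 3-D array.
#' @param label one of `"lung"`, `"airway_lumen"`, `"airway_wall"`,
#'   `"analysis"`, `"other"`.
#' @export
region_mask <- function(mask, label = "other", spacing = c(1, 1, 1)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stopf("`mask` must be a 3-D logical array")
  storage.mode(mask) <- "logical"
  label <- match.arg(label,
    c("lung", "airway_lumen", "airway_wall", "analysis", "other"))
  structure(list(mask = mask, label = label, spacing = rep3(spacing, "spacing")),
            class = "region_mask")
}

#' @rdname ct_volume
#' @param volume a `ct_volume`.
#' @return `voxel_volume_ml()` returns the volume of one voxel in mL.
#' @export
voxel_volume_ml <- function(volume) prod(volume$spacing) / 1000

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask:%s> %s voxels, %d in mask\n", x$label,
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$mask)))
    stopf("mask shape (%s) does not match volume shape (%s)",
          paste(dim(mask$mask), collapse = "x"),
          paste(dim(volume$values), collapse = "x"))
  invisible(TRUE)
}

#' Read and write volumes and masks as NIfTI
#'
#' Volumes are stored as 32-bit float NIfTI with the voxel spacing in the
#' `pixdim` header; masks as uint8.  Reading recovers values and spacing.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a `ct_volume`; `read_mask()` a
#'   `region_mask`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  ct_volume(arr, spacing = spacing)
}

#' @rdname read_volume
#' @param volume a `ct_volume`.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$values
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, label = "other") {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img) != 0, dim = dim(img)[1:3])
  region_mask(arr, label = label, spacing = spacing)
}

#' @rdname read_volume
#' @param mask a `region_mask`.
#' @export
write_mask <- function(mask, path) {
  arr <- array(as.integer(mask$mask), dim = dim(mask$mask))
  attr(arr, "pixdim") <- mask$spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# voxel-centre mm coordinates of 1-based indices (n x 3 matrix or vector)
voxel_to_mm <- function(idx, spacing, origin = c(0, 0, 0)) {
  idx <- rbind(idx)
  sweep(sweep(idx - 0.5, 2, spacing, "*"), 2, origin, "+")
}

mm_to_voxel0 <- function(pts, spacing, origin = c(0, 0, 0)) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") - 0.5
}
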
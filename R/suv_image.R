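#' SUV image container
#'
#' A minimal container for a 3-D standardized-uptake-value (SUV) grid:
#' the voxel values, the voxel spacing in mm and the world-space origin.
#' Voxel indices are 0-based throughout the package and the world coordinate
#' of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param values 3-D numeric array of nonnegative, finite SUVs.
#' @param spacing Voxel spacing in mm (length 3, positive).
#' @param origin World coordinate of voxel (0, 0, 0) in mm (length 3).
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("'values' must be a 3-D array")
  if (any(!is.finite(values))) stopf("SUV values must be finite")
  if (any(values < 0)) stopf("SUV values must be nonnegative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("'spacing' must be 3 positive values (mm)")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "suv_image"
  )
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image> %s voxels @ %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in ml
#' @param image A `suv_image` (or anything with a `spacing` field).
#' @return Scalar volume of one voxel in ml (= cc).
#' @export
voxel_volume_ml <- function(image) prod(image$spacing) / 1000

# World coordinates (mm) of 0-based voxel indices (n x 3 matrix).
voxel_to_world <- function(image, idx) {
  sweep(sweep(idx, 2, image$spacing, `*`), 2, image$origin, `+`)
}

#' Read / write SUV volumes and label maps as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that preserve voxel spacing. Label maps are
#' written as integer volumes.
#'
#' @param image A `suv_image`, or for `write_labelmap_nifti` an integer array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm for label maps.
#' @return `read_suv_nifti` returns a `suv_image`; writers return the path.
#' @export
write_suv_nifti <- function(image, path) {
  nim <- RNifti::asNifti(image$values)
  RNifti::pixdim(nim) <- image$spacing
  write_atomic(function(p) RNifti::writeNifti(nim, p), path)
}

#' @rdname write_suv_nifti
#' @export
read_suv_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  suv_image(array(as.numeric(nim), dim = dim(nim)), RNifti::pixdim(nim)[1:3])
}

#' @rdname write_suv_nifti
#' @export
write_labelmap_nifti <- function(image, path, spacing) {
  arr <- if (is.list(image)) image$values else image
  nim <- RNifti::asNifti(array(as.integer(arr), dim = dim(arr)))
  RNifti::pixdim(nim) <- spacing
  nim <- RNifti::asNifti(nim, datatype = "int32")
  write_atomic(function(p) RNifti::writeNifti(nim, p), path)
}

#' @rdname write_suv_nifti
#' @export
read_labelmap_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  list(values = array(as.integer(nim), dim = dim(nim)),
       spacing = RNifti::pixdim(nim)[1:3])
}
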
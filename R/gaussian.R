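#' Separable 3-D Gaussian filtering
#'
#' Convolves a 3-D volume with an axis-aligned Gaussian kernel, applied as
#' three 1-D passes. Used both to emulate the scanner point-spread function
#' (PSF) in the phantom generator and to smooth images before gradient-based
#' segmentation.
#'
#' @param vol 3-D numeric array.
#' @param sigma_mm Gaussian standard deviation in mm (scalar, isotropic).
#' @param spacing Voxel spacing in mm, length 3.
#' @param normalize_edges If `TRUE`, truncated kernels at the volume boundary
#'   are renormalized to sum to one (appropriate for smoothing); if `FALSE`,
#'   signal is allowed to spill out of the grid (appropriate for a PSF, which
#'   conserves activity rather than local means).
#' @return Array of the same dimension.
#' @export
gaussian_blur_3d <- function(vol, sigma_mm, spacing, normalize_edges = TRUE) {
  stopifnot(length(dim(vol)) == 3L, length(spacing) == 3L, all(spacing > 0))
  assert_scalar_num(sigma_mm, "sigma_mm", lower = 0)
  if (sigma_mm == 0) return(vol)
  for (axis in 1:3) {
    vol <- blur_axis(vol, axis, sigma_mm / spacing[axis], normalize_edges)
  }
  vol
}

# 1-D Gaussian convolution along one axis via a banded dense matrix and BLAS.
blur_axis <- function(vol, axis, sigma_vox, normalize_edges) {
  n <- dim(vol)[axis]
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  k <- exp(-0.5 * (offs / sigma_vox)^2)
  k <- k / sum(k)
  # K[i, j] = kernel weight from source j to target i
  K <- matrix(0, n, n)
  for (m in seq_along(offs)) {
    j <- seq_len(n) + offs[m]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[m]
  }
  if (normalize_edges) K <- K / rowSums(K)
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- K %*% matrix(v, nrow = dv[1])
  dim(v) <- dv
  aperm(v, order(perm))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
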
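#' Lesion specification for the synthetic phantom
#'
#' Describes one synthetic lesion: an ellipsoidal (or spherical) region with a
#' target SUV level, Gaussian voxel noise, and an optional linear radial
#' gradient so the rim is colder than the core before PSF blurring.
#'
#' @param center Lesion centre in world mm (length 3).
#' @param semi_axes Ellipsoid semi-axes in mm (length 3); pass a single radius
#'   via `radius` for a sphere.
#' @param radius Sphere radius in mm (shorthand for equal `semi_axes`).
#' @param organ_label One of `"liver"`, `"bone"`, `"node"`, `"soft_tissue"`.
#' @param target_suv_mean Core SUV before blurring (must exceed background).
#' @param target_suv_sd Voxelwise Gaussian noise SD inside the lesion.
#' @param radial_gradient_fraction Fraction in `[0, 1]` of SUV dropped
#'   linearly from core to rim before blurring.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radius = NULL, semi_axes = NULL,
                        organ_label = c("liver", "bone", "node", "soft_tissue"),
                        target_suv_mean = 10, target_suv_sd = 0.5,
                        radial_gradient_fraction = 0) {
  organ_label <- match.arg(organ_label)
  if (is.null(semi_axes)) {
    assert_scalar_num(radius, "radius", lower = 0, strict = TRUE)
    semi_axes <- rep(radius, 3)
  }
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stopf("'semi_axes' must be 3 positive values (mm)")
  assert_scalar_num(target_suv_mean, "target_suv_mean", lower = 0)
  assert_scalar_num(target_suv_sd, "target_suv_sd", lower = 0)
  assert_scalar_num(radial_gradient_fraction, "radial_gradient_fraction",
                    lower = 0)
  if (radial_gradient_fraction > 1)
    stopf("'radial_gradient_fraction' must be in [0, 1]")
  structure(list(center = as.numeric(center), semi_axes = semi_axes,
                 organ_label = organ_label,
                 target_suv_mean = target_suv_mean,
                 target_suv_sd = target_suv_sd,
                 radial_gradient_fraction = radial_gradient_fraction),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Geometry and intensity model for one synthetic whole-body PET phantom:
#' Gaussian background, an ellipsoidal liver with physiologic uptake, a list
#' of lesions, and an isotropic Gaussian PSF. Defaults follow a clinical
#' somatostatin-receptor PET scale: background SUV 0.5 +/- 0.1, liver
#' 6.0 +/- 0.5, PSF FWHM 6 mm.
#'
#' @param grid_shape Voxels per axis (length 3, positive integers).
#' @param voxel_spacing Voxel spacing in mm (length 3 or scalar).
#' @param background_suv_mean,background_suv_sd Background SUV level / noise.
#' @param liver_center,liver_semi_axes Liver ellipsoid geometry in mm, or
#'   `NULL` for no liver.
#' @param liver_suv_mean,liver_suv_sd Liver SUV level / noise.
#' @param psf_fwhm_mm Full width at half maximum of the PSF (>= 0).
#' @param lesions List of [lesion_spec()] objects.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48), voxel_spacing = 3,
                         background_suv_mean = 0.5, background_suv_sd = 0.1,
                         liver_center = NULL, liver_semi_axes = c(60, 45, 40),
                         liver_suv_mean = 6.0, liver_suv_sd = 0.5,
                         psf_fwhm_mm = 6, lesions = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stopf("'grid_shape' must be 3 positive integers")
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3)
  if (any(voxel_spacing <= 0)) stopf("'voxel_spacing' must be positive")
  assert_scalar_num(background_suv_mean, "background_suv_mean", lower = 0)
  assert_scalar_num(psf_fwhm_mm, "psf_fwhm_mm", lower = 0)
  assert_scalar_num(liver_suv_mean, "liver_suv_mean", lower = 0)
  extent <- grid_shape * voxel_spacing
  if (is.null(liver_center) && !is.null(liver_semi_axes))
    liver_center <- extent * c(0.3, 0.35, 0.55)
  for (ls in lesions) {
    if (!inherits(ls, "lesion_spec")) stopf("'lesions' must be lesion_spec objects")
    if (ls$target_suv_mean <= background_suv_mean)
      stopf("lesion target_suv_mean must exceed the background")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_suv_mean = background_suv_mean,
                 background_suv_sd = background_suv_sd,
                 liver_center = liver_center,
                 liver_semi_axes = liver_semi_axes,
                 liver_suv_mean = liver_suv_mean, liver_suv_sd = liver_suv_sd,
                 psf_fwhm_mm = psf_fwhm_mm, lesions = lesions),
            class = "phantom_spec")
}

# Logical mask of voxel centres inside an ellipsoid, plus the normalized
# radius of each in-mask voxel (0 at centre, 1 on the surface).
ellipsoid_mask <- function(grid_shape, spacing, center, semi_axes,
                           origin = c(0, 0, 0)) {
  ax <- origin[1] + (seq_len(grid_shape[1]) - 1) * spacing[1]
  ay <- origin[2] + (seq_len(grid_shape[2]) - 1) * spacing[2]
  az <- origin[3] + (seq_len(grid_shape[3]) - 1) * spacing[3]
  dx2 <- ((ax - center[1]) / semi_axes[1])^2
  dy2 <- ((ay - center[2]) / semi_axes[2])^2
  dz2 <- ((az - center[3]) / semi_axes[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  list(mask = r2 <= 1, rho = sqrt(r2))
}

#' Generate a synthetic PET phantom
#'
#' Builds an SUV volume as background noise + liver ellipsoid + lesions,
#' convolves it with an isotropic Gaussian PSF, and clips at zero. The label
#' map assigns each lesion the consecutive positive integers `1..K` and liver
#' parenchyma the reserved value [LIVER_LABEL]. The truth table records, per
#' lesion, the analytic ellipsoid volume, the voxelized volume, and the
#' pre-blur SUV statistics of its voxels.
#'
#' Lesions must not overlap each other (so per-lesion ground truth stays
#' unambiguous) and must lie fully inside the grid; violations are errors.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the phantom is deterministic given `(spec, seed)`.
#' @return List with `image` (a [suv_image()]), `label_map` (integer array),
#'   `liver_mask` (logical array, `NULL` when the phantom has no liver) and
#'   `truth` (data frame, one row per lesion).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape; sp <- spec$voxel_spacing
  extent <- (g - 1) * sp
  with_seed(seed, {
    vol <- array(rnorm(prod(g), spec$background_suv_mean,
                       spec$background_suv_sd), dim = g)
    liver_mask <- NULL
    if (!is.null(spec$liver_semi_axes)) {
      em <- ellipsoid_mask(g, sp, spec$liver_center, spec$liver_semi_axes)
      liver_mask <- em$mask
      vol[liver_mask] <- rnorm(sum(liver_mask), spec$liver_suv_mean,
                               spec$liver_suv_sd)
    }
    label_map <- array(0L, dim = g)
    truth <- vector("list", length(spec$lesions))
    for (k in seq_along(spec$lesions)) {
      ls <- spec$lesions[[k]]
      if (any(ls$center - ls$semi_axes < 0) ||
          any(ls$center + ls$semi_axes > extent))
        stopf("lesion %d extends outside the grid", k)
      em <- ellipsoid_mask(g, sp, ls$center, ls$semi_axes)
      if (!any(em$mask)) stopf("lesion %d covers no voxel centre", k)
      if (any(label_map[em$mask] > 0L))
        stopf("lesion %d overlaps a previously placed lesion", k)
      rho <- em$rho[em$mask]
      level <- ls$target_suv_mean * (1 - ls$radial_gradient_fraction * rho)
      suv <- rnorm(length(level), level, ls$target_suv_sd)
      suv <- pmax(suv, 0)
      vol[em$mask] <- suv
      label_map[em$mask] <- k
      truth[[k]] <- data.frame(
        lesion_id = k, organ_label = ls$organ_label,
        analytic_volume_ml = 4 / 3 * pi * prod(ls$semi_axes) / 1000,
        voxel_volume_ml = sum(em$mask) * prod(sp) / 1000,
        n_voxels = sum(em$mask),
        preblur_suv_mean = mean(suv), preblur_suv_max = max(suv),
        preblur_suv_sd = stats::sd(suv) * sqrt((length(suv) - 1) / length(suv)),
        target_suv_mean = ls$target_suv_mean)
    }
    if (spec$psf_fwhm_mm > 0)
      vol <- gaussian_blur_3d(vol, fwhm_to_sigma(spec$psf_fwhm_mm), sp,
                              normalize_edges = FALSE)
    vol <- pmax(vol, 0)
    if (!is.null(liver_mask))
      label_map[liver_mask & label_map == 0L] <- LIVER_LABEL
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(lesion_id = integer(), organ_label = character(),
                 analytic_volume_ml = numeric(), voxel_volume_ml = numeric(),
                 n_voxels = integer(), preblur_suv_mean = numeric(),
                 preblur_suv_max = numeric(), preblur_suv_sd = numeric(),
                 target_suv_mean = numeric())
    list(image = suv_image(vol, sp), label_map = label_map,
         liver_mask = liver_mask, truth = truth)
  })
}
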
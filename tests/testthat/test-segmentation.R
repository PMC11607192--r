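cfg_default <- segmentation_config()

test_that("icosphere subdivision yields 10 f^2 + 2 unit directions", {
  for (f in c(1, 2, 3)) {
    d <- icosphere_directions(f)
    expect_equal(nrow(d), 10 * f^2 + 2)
    expect_equal(rowSums(d^2), rep(1, nrow(d)), tolerance = 1e-12)
  }
})

test_that("three disjoint hot spheres give exactly three seeds inside truth", {
  centers <- list(c(30, 30, 30), c(64, 60, 34), c(40, 66, 64))
  sp <- phantom_spec(grid_shape = c(48, 48, 48), voxel_spacing = 2,
                     background_suv_mean = 0.5, background_suv_sd = 0.1,
                     liver_semi_axes = NULL, psf_fwhm_mm = 6,
                     lesions = lapply(centers, function(ctr)
                       lesion_spec(center = ctr, radius = 9,
                                   target_suv_mean = 10, target_suv_sd = 0.5,
                                   organ_label = "node")))
  ph <- generate_phantom(sp, seed = 2)
  seeds <- detect_candidate_seeds(ph$image, cfg = cfg_default)
  expect_equal(nrow(seeds), 3)
  labels <- ph$label_map[seeds + 1L]
  expect_setequal(labels, 1:3)
})

test_that("uniform or sub-threshold images yield no seeds", {
  img <- suv_image(array(3, c(20, 20, 20)), c(3, 3, 3))
  liver <- liver_reference(3)
  expect_equal(nrow(detect_candidate_seeds(img, liver, cfg_default)), 0)
  ph <- sphere_phantom(9, suv = 6, seed = 3)
  cfg_hi <- segmentation_config(min_seed_suv_multiple_of_liver = 3)
  expect_equal(nrow(detect_candidate_seeds(ph$image, liver_reference(6),
                                           cfg_hi)), 0)
})

test_that("an unblurred sphere is recovered within one voxel shell", {
  ph <- sphere_phantom(8, fwhm = 0, noise = 0, bg = 0, bg_sd = 0)
  seg <- segment_lesion(ph$image, c(23, 23, 23), cfg_default)
  vol_true <- 4 / 3 * pi * 0.8^3
  shell <- 4 * pi * 0.8^2 * 0.2  # one voxel-layer on the surface
  expect_lt(abs(seg$volume_ml - vol_true), shell)
})

test_that("blurred spheres are recovered with high Dice and bounded volume error", {
  for (R in c(8, 12)) {
    ph <- sphere_phantom(R, fwhm = 6, seed = 7)
    seeds <- detect_candidate_seeds(ph$image, cfg = cfg_default)
    seg <- segment_lesion(ph$image, seeds[1, ], cfg_default)
    truth <- which(ph$label_map == 1, arr.ind = TRUE) - 1L
    vol_true <- 4 / 3 * pi * (R / 10)^3
    expect_gte(dice_coef(seg$voxels, truth), 0.80)
    expect_lte(abs(seg$volume_ml - vol_true) / vol_true, 0.20)
  }
})

test_that("raw gradient-boundary volume error decreases as the PSF narrows", {
  # the bias-corrected boundary removes the systematic PSF effect, so the
  # monotone property is checked on the uncorrected gradient boundary
  cfg_raw <- segmentation_config(curvature_correction = FALSE)
  err <- sapply(c(6, 2), function(fw) {
    ph <- sphere_phantom(10, fwhm = fw, seed = 9)
    seg <- segment_lesion(ph$image, c(23, 23, 23), cfg_raw)
    abs(seg$volume_ml - 4 / 3 * pi)
  })
  expect_lt(err[2], err[1])
})

test_that("flat regions are rejected as non-lesions", {
  img <- suv_image(array(5, c(24, 24, 24)), c(3, 3, 3))
  expect_error(segment_lesion(img, c(12, 12, 12), cfg_default),
               "not a lesion")
  ph <- sphere_phantom(9, seed = 4)
  expect_error(segment_lesion(ph$image, c(200, 1, 1), cfg_default),
               "outside")
})

test_that("segmentation is equivariant to whole-voxel translations", {
  ph1 <- sphere_phantom(9, fwhm = 6, noise = 0, bg = 0, bg_sd = 0,
                        center = c(40, 40, 40))
  ph2 <- sphere_phantom(9, fwhm = 6, noise = 0, bg = 0, bg_sd = 0,
                        center = c(40, 40, 40) + c(6, 4, 2))
  s1 <- segment_lesion(ph1$image, c(20, 20, 20), cfg_default)
  s2 <- segment_lesion(ph2$image, c(23, 22, 21), cfg_default)
  shifted <- sweep(s1$voxels, 2, c(3L, 2L, 1L), `+`)
  expect_equal(dice_coef(shifted, s2$voxels), 1)
})

test_that("segments are 26-connected and deterministic", {
  ph <- sphere_phantom(10, seed = 6)
  s1 <- segment_lesion(ph$image, c(23, 23, 23), cfg_default)
  s2 <- segment_lesion(ph$image, c(23, 23, 23), cfg_default)
  expect_identical(s1$voxels, s2$voxels)
  comp <- ssthet:::connected_component(s1$voxels, s1$seed)
  expect_equal(nrow(comp), nrow(s1$voxels))
})

test_that("liver reference: constant region, lesion exclusion, noisy sampling", {
  sp <- phantom_spec(grid_shape = c(40, 40, 32), voxel_spacing = 4,
                     background_suv_mean = 0.5, background_suv_sd = 0,
                     liver_center = c(80, 80, 64),
                     liver_semi_axes = c(55, 45, 40),
                     liver_suv_mean = 6, liver_suv_sd = 0, psf_fwhm_mm = 0)
  ph <- generate_phantom(sp, seed = 1)
  ref <- extract_liver_reference(ph$image, ph$liver_mask)
  expect_equal(ref$liver_suv_mean, 6, tolerance = 1e-12)
  expect_equal(ref$liver_suv_max, 6, tolerance = 1e-12)

  # a lesion occupying much of the liver is excluded from the VOI
  lesion_mask <- ph$liver_mask
  lesion_mask[, 1:20, ] <- FALSE  # keep lesion on one side only
  ref2 <- suppressWarnings(
    extract_liver_reference(ph$image, ph$liver_mask, lesion_mask))
  vox_liver_free <- sum(ph$liver_mask & !lesion_mask)
  expect_lte(ref2$reference_voxel_count, vox_liver_free)

  # noisy liver: VOI mean within 3 SE of truth
  sp$liver_suv_sd <- 0.5
  ph3 <- generate_phantom(sp, seed = 8)
  ref3 <- extract_liver_reference(ph3$image, ph3$liver_mask)
  se <- 0.5 / sqrt(ref3$reference_voxel_count)
  expect_lt(abs(ref3$liver_suv_mean - 6), 3 * se)
  expect_error(extract_liver_reference(ph$image, array(FALSE, dim(ph$liver_mask))),
               "no lesion-free liver")
})
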
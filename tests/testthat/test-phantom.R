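test_that("a phantom with no lesions is liver plus background", {
  sp <- phantom_spec(grid_shape = c(32, 32, 24), voxel_spacing = 4,
                     background_suv_mean = 0.5, background_suv_sd = 0.05,
                     liver_semi_axes = c(40, 30, 25), liver_suv_mean = 6,
                     psf_fwhm_mm = 6)
  ph <- generate_phantom(sp, seed = 1)
  expect_equal(nrow(ph$truth), 0)
  expect_setequal(unique(as.integer(ph$label_map)), c(0L, LIVER_LABEL))
  expect_lt(abs(max(ph$image$values) - 6), 1)
  expect_lt(mean(ph$image$values[ph$label_map == 0]), 2)
})

test_that("voxelized sphere volume approaches the analytic volume as spacing shrinks", {
  vol_true <- 4 / 3 * pi * 1.0^3  # 10 mm radius -> 4.18879 ml
  errs <- sapply(c(2, 1), function(h) {
    grid <- round(60 / h)
    ph <- sphere_phantom(10, fwhm = 0, spacing = h, grid = grid,
                         noise = 0, bg = 0, bg_sd = 0)
    abs(ph$truth$voxel_volume_ml - vol_true)
  })
  expect_equal(4 / 3 * pi * 1.0^3, 4.18879, tolerance = 1e-5)
  # error bounded by one voxel shell (4 pi R^2 h) and shrinking with h
  expect_lt(errs[1], 4 * pi * 1.0^2 * 0.2)
  expect_lt(errs[2], 4 * pi * 1.0^2 * 0.1)
  expect_lt(errs[2], errs[1])
})

test_that("same spec under different seeds gives identical masks, different noise", {
  ph1 <- sphere_phantom(8, seed = 1)
  ph2 <- sphere_phantom(8, seed = 2)
  expect_identical(ph1$label_map, ph2$label_map)
  expect_false(identical(ph1$image$values, ph2$image$values))
  ph1b <- sphere_phantom(8, seed = 1)
  expect_identical(ph1$image$values, ph1b$image$values)
})

test_that("overlapping or out-of-grid lesions are rejected", {
  mk <- function(centers) {
    phantom_spec(grid_shape = c(32, 32, 32), voxel_spacing = 3,
                 liver_semi_axes = NULL, psf_fwhm_mm = 0,
                 lesions = lapply(centers, function(ctr)
                   lesion_spec(center = ctr, radius = 10,
                               target_suv_mean = 8,
                               organ_label = "bone")))
  }
  expect_error(generate_phantom(mk(list(c(45, 45, 45), c(50, 45, 45))), 1),
               "overlap")
  expect_error(generate_phantom(mk(list(c(5, 45, 45))), 1), "outside")
})

test_that("PSF blur cannot raise the mean SUV of a hot lesion", {
  for (R in c(6, 10)) {
    ph <- sphere_phantom(R, fwhm = 6, noise = 0.2, seed = 3)
    seg <- lesions_from_labelmap(ph$image, ph$label_map)[[1]]
    expect_lt(mean(seg$suv), ph$truth$preblur_suv_mean)
  }
})

test_that("truth table records pre-blur statistics of the assigned voxels", {
  ph <- sphere_phantom(10, fwhm = 0, noise = 0.5, seed = 5)
  seg <- lesions_from_labelmap(ph$image, ph$label_map)[[1]]
  # with no PSF the in-mask voxels are exactly the pre-blur draws
  expect_equal(mean(seg$suv), ph$truth$preblur_suv_mean, tolerance = 1e-12)
  expect_equal(max(seg$suv), ph$truth$preblur_suv_max, tolerance = 1e-12)
  s <- brute_stats(seg$suv)
  expect_equal(ph$truth$preblur_suv_sd, s$sd, tolerance = 1e-12)
})

test_that("radial gradient lowers rim SUV relative to core before blur", {
  sp <- phantom_spec(grid_shape = c(40, 40, 40), voxel_spacing = 2,
                     background_suv_mean = 0, background_suv_sd = 0,
                     liver_semi_axes = NULL, psf_fwhm_mm = 0,
                     lesions = list(lesion_spec(center = c(39, 39, 39),
                                                radius = 12,
                                                target_suv_mean = 10,
                                                target_suv_sd = 0,
                                                radial_gradient_fraction = 0.5,
                                                organ_label = "liver")))
  ph <- generate_phantom(sp, seed = 1)
  seg <- lesions_from_labelmap(ph$image, ph$label_map)[[1]]
  ctr <- c(39, 39, 39) / 2  # voxel coordinates of the centre
  r <- sqrt(rowSums(sweep(seg$voxels, 2, ctr)^2)) * 2
  core <- seg$suv[r < 4]; rim <- seg$suv[r > 10]
  expect_gt(mean(core), mean(rim))
  expect_equal(max(seg$suv), 10, tolerance = 0.2)
})
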
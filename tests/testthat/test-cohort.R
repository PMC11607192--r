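small_config <- function(...) {
  cohort_config(n_patients = 3, lesions_per_patient = c(3, 3),
                phantom = phantom_spec(grid_shape = c(40, 40, 32),
                                       voxel_spacing = 4), ...)
}

test_that("lesion truth table rows equal patients x lesions", {
  b <- generate_cohort(small_config(), seed = 5)
  expect_equal(nrow(b$lesion_table), 9)
  expect_equal(length(unique(b$lesion_table$patient_id)), 3)
  truth_rows <- sum(vapply(b$patients, function(p) nrow(p$truth), 1L))
  expect_equal(truth_rows, 9)
  expect_true(all(b$lesion_table$organ_label %in%
                    c("liver", "bone", "node", "soft_tissue")))
})

test_that("single-lesion patients are flagged ineligible with a warning", {
  cfg <- cohort_config(n_patients = 2, lesions_per_patient = c(1, 1),
                       phantom = phantom_spec(grid_shape = c(40, 40, 32),
                                              voxel_spacing = 4))
  w <- capture_warnings(b <- generate_cohort(cfg, seed = 2))
  expect_true(any(grepl("ineligible", w)))
  expect_false(any(b$patient_table$eligible_patient))
})

test_that("a fixed (config, seed) reproduces byte-identical CSV outputs", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  b1 <- generate_cohort(small_config(), seed = 9, keep_images = FALSE)
  b2 <- generate_cohort(small_config(), seed = 9, keep_images = FALSE)
  write_cohort(b1, d1); write_cohort(b2, d2)
  for (f in c("lesion_features.csv", "patient_features.csv",
              "lesion_truth.csv", "survival.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  b3 <- generate_cohort(small_config(), seed = 10, keep_images = FALSE)
  expect_false(identical(b1$survival$time_months, b3$survival$time_months))
})

test_that("survival records honour truncation and endpoint labels", {
  b <- generate_cohort(small_config(), seed = 4)
  ttp <- b$survival[b$survival$endpoint == "TTP24", ]
  expect_true(all(ttp$time_months <= 24))
  expect_setequal(unique(b$survival$endpoint), c("TTP24", "OS"))
  expect_equal(nrow(b$survival), 2 * 3)
})

test_that("NIfTI round trip preserves the SUV volume and label map", {
  b <- generate_cohort(small_config(), seed = 7)
  d <- file.path(tempdir(), "niftis")
  write_cohort(b, d)
  img <- read_suv_nifti(file.path(d, "suv_p001.nii.gz"))
  expect_equal(img$values, b$patients[[1]]$image$values, tolerance = 1e-6)
  expect_equal(img$spacing, b$patients[[1]]$image$spacing)
  lm <- read_labelmap_nifti(file.path(d, "labels_p001.nii.gz"))
  expect_identical(lm$values, b$patients[[1]]$label_map)
})

test_that("YAML configuration maps onto the cohort generator", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 4",
    "lesions_per_patient: [2, 3]",
    "phantom:",
    "  grid_shape: [40, 40, 32]",
    "  voxel_spacing: 4",
    "  psf_fwhm_mm: 5",
    "ttp:",
    "  baseline_hazard: 0.05",
    "  censoring_max: 30",
    "  admin_truncation_months: 24",
    "  true_coefficients:",
    "    total_volume_ml: 0.5"), f)
  cfg <- read_cohort_config(f)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_patients, 4L)
  expect_equal(cfg$phantom$psf_fwhm_mm, 5)
  expect_equal(cfg$ttp_spec$true_coefficients, c(total_volume_ml = 0.5))
  expect_equal(cfg$ttp_spec$admin_truncation_months, 24)
  expect_equal(cfg$os_spec$endpoint, "OS")  # untouched default
  b <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(b$patient_table), 4)
})
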
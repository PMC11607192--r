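test_that("histogram statistics match hand-computed examples", {
  s <- compute_histogram_stats(c(5, 5, 5, 5))
  expect_equal(s$mean, 5); expect_equal(s$max, 5)
  expect_equal(s$sd, 0); expect_equal(s$cv, 0)
  expect_true(is.na(s$skewness)); expect_true(is.na(s$kurtosis))

  expect_equal(compute_histogram_stats(c(1, 2, 3))$skewness, 0)

  s <- compute_histogram_stats(c(1, 1, 1, 5))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(3), tolerance = 1e-12)
  expect_equal(s$skewness, 6 / 3^1.5, tolerance = 1e-12)

  expect_error(compute_histogram_stats(numeric()), "empty")
  expect_error(compute_histogram_stats(c(1, -2)), "nonnegative")
})

test_that("intra-lesional record reproduces the defining products and ratios", {
  vox <- cbind(1:10, 1L, 1L)
  seg <- ssthet:::new_lesion_segment(1L, 1L, "liver", vox, rep(5, 10), 0.2)
  liver <- liver_reference(4, 5)
  rec <- compute_intralesional_features(seg, liver)
  expect_equal(rec$volume_ml, 2.0)
  expect_equal(rec$receptor_expression, 10.0)        # 2.0 ml x SUVmean 5
  expect_equal(rec$liver_corrected_suv_mean, 1.25)   # 5 / 4
  expect_equal(rec$liver_corrected_receptor_expression, 2.5)
  expect_true(rec$eligible)

  seg2 <- ssthet:::new_lesion_segment(2L, 1L, "bone", vox,
                                      c(rep(8, 9), 12), 0.2)
  rec2 <- compute_intralesional_features(seg2, liver_reference(4, 4))
  expect_equal(rec2$max_over_mean, 12 / rec2$suv_mean)
  expect_equal(rec2$excess_over_mean, (12 - rec2$suv_mean) / rec2$suv_mean)
  expect_equal(rec2$liver_corrected_suv_max, 3)        # 12 / liver max 4
  expect_equal(rec2$liver_corrected_suv_max_lmean, 3)  # 12 / liver mean 4

  expect_error(compute_intralesional_features(seg, liver_reference(1e-12)),
               NA)  # tiny but positive liver mean is allowed
})

test_that("volume filter keeps the boundary and preserves all records", {
  segs <- lapply(c(0.3, 0.524, 1.0), function(v) {
    nv <- max(1L, round(v / 0.1))
    ssthet:::new_lesion_segment(1L, 1L, "node", cbind(seq_len(nv), 1L, 1L),
                                rep(3, nv), v / nv)
  })
  tab <- lesion_feature_table(segs, liver_reference(5))
  flt <- apply_volume_filter(tab)
  expect_equal(nrow(flt$eligible), 2)
  expect_equal(nrow(flt$all), 3)
  expect_true(0.524 %in% round(flt$eligible$volume_ml, 6))
  # empty input
  e <- apply_volume_filter(tab[0, ])
  expect_equal(nrow(e$eligible), 0); expect_equal(nrow(e$all), 0)
})

test_that("all 14 indices match brute-force recomputation on 100 random lesions", {
  set.seed(11)
  liver <- liver_reference(6.1, 8.3)
  worst <- 0
  for (k in 1:100) {
    seg <- random_segment(k)
    rec <- compute_intralesional_features(seg, liver)
    oracle <- brute_lesion_features(seg$suv, seg$volume_ml,
                                    liver$liver_suv_mean,
                                    liver$liver_suv_max)
    got <- unlist(rec[names(oracle)])
    rel <- abs(got - oracle) / pmax(abs(oracle), 1e-300)
    rel <- rel[!is.na(oracle)]
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
})

test_that("indices are scale-equivariant in the expected pattern", {
  set.seed(21)
  seg <- random_segment(1)
  liver <- liver_reference(5.5, 7.0)
  c0 <- compute_intralesional_features(seg, liver)
  cc <- 3.7
  seg2 <- seg; seg2$suv <- seg$suv * cc
  liver2 <- liver_reference(5.5 * cc, 7.0 * cc)
  c1 <- compute_intralesional_features(seg2, liver2)
  invariant <- c("skewness", "kurtosis", "cv_suv", "max_over_mean",
                 "excess_over_mean", "liver_corrected_receptor_expression",
                 "liver_corrected_suv_mean", "liver_corrected_suv_max",
                 "liver_corrected_suv_max_lmean", "volume_ml")
  for (f in invariant) expect_equal(c1[[f]], c0[[f]], tolerance = 1e-10)
  for (f in c("suv_mean", "suv_max", "sd_suv", "receptor_expression"))
    expect_equal(c1[[f]], cc * c0[[f]], tolerance = 1e-10)
  # ratio of expression to its liver-corrected version is the liver mean
  expect_equal(c0$receptor_expression /
                 c0$liver_corrected_receptor_expression,
               liver$liver_suv_mean, tolerance = 1e-12)
})

test_that("histogram conventions are configurable", {
  x <- c(1, 2, 3, 10)
  s_pop <- compute_histogram_stats(x, sd_divisor = "n")
  s_smp <- compute_histogram_stats(x, sd_divisor = "n-1")
  expect_equal(s_smp$sd, sd(x))
  expect_equal(s_pop$sd, sd(x) * sqrt(3 / 4))
  k_exc <- compute_histogram_stats(x, kurtosis_excess = TRUE)$kurtosis
  k_raw <- compute_histogram_stats(x, kurtosis_excess = FALSE)$kurtosis
  expect_equal(k_raw - k_exc, 3)
})
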
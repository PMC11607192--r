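# Builds a small lesion table directly, bypassing segmentation.
lesion_row <- function(pid, id, organ, volume, suv_mean, suv_max,
                       liver = liver_reference(4, 5)) {
  nv <- 10
  suv <- rep(suv_mean, nv); suv[1] <- suv_max
  suv[2] <- 2 * suv_mean - suv_max  # keep the mean at suv_mean
  seg <- ssthet:::new_lesion_segment(id, pid, organ,
                                     cbind(seq_len(nv), 1L, 1L), suv,
                                     volume / nv)
  compute_intralesional_features(seg, liver)
}

test_that("cosine dissimilarity closed forms", {
  expect_equal(cosine_dissimilarity(c(1, 2, 3), c(2, 4, 6)), 0,
               tolerance = 1e-15)
  expect_equal(cosine_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_dissimilarity(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_warning(v <- cosine_dissimilarity(c(0, 0), c(1, 0)), "zero")
  expect_true(is.na(v))
  expect_error(cosine_dissimilarity(1:2, 1:3), "equal")
})

test_that("mean/max/SD summaries follow hand computation and n<2 rules", {
  tab <- rbind(lesion_row(1, 1, "liver", 1, 2, 3),
               lesion_row(1, 2, "bone", 1, 4, 5),
               lesion_row(1, 3, "node", 1, 6, 7))
  s <- summarize_intralesional(tab)
  expect_equal(unname(s["mean_suv_mean"]), 4)
  expect_equal(unname(s["max_suv_mean"]), 6)
  expect_equal(unname(s["sd_suv_mean"]), 2)  # sample SD of 2,4,6
  expect_equal(length(s), 42)

  one <- summarize_intralesional(tab[1, ])
  expect_equal(unname(one["mean_suv_mean"]), 2)
  expect_true(all(is.na(one[grep("^sd_", names(one))])))

  same <- summarize_intralesional(rbind(tab[1, ], tab[1, ]))
  sds <- same[grep("^sd_", names(same))]
  expect_true(all(sds[!is.na(sds)] == 0))

  expect_warning(empty <- summarize_intralesional(tab[0, ]), "no eligible")
  expect_true(all(is.na(empty)))
})

test_that("totals use all lesions for volume/count, eligible for expression", {
  all_tab <- rbind(lesion_row(1, 1, "liver", 0.3, 5, 6),
                   lesion_row(1, 2, "bone", 1.0, 5, 6))
  eli <- all_tab[all_tab$volume_ml >= 0.524, ]
  tot <- compute_totals(all_tab, eli)
  expect_equal(unname(tot["total_volume_ml"]), 1.3)
  expect_equal(unname(tot["n_lesions"]), 2)
  expect_equal(unname(tot["total_receptor_expression"]), 1.0 * 5)
  z <- compute_totals(all_tab[0, ], eli[0, ])
  expect_true(all(z == 0))
})

test_that("spread indices reproduce the three defining formulas", {
  tab <- rbind(lesion_row(1, 1, "liver", 1, 8, 10),
               lesion_row(1, 2, "bone", 1, 4, 5),
               lesion_row(1, 3, "node", 1, 1.5, 2))
  sp <- compute_spread_indices(tab)
  expect_equal(unname(sp["max_suvmax_over_min_suvmax"]), 5.0)     # 10 / 2
  expect_equal(unname(sp["max_suvmax_minus_min_suvmean"]), 8.5)   # 10 - 1.5
  expect_equal(unname(sp["max_of_suvmax_minus_suvmean"]), 2.0)

  one <- compute_spread_indices(tab[1, ])
  expect_equal(unname(one["max_suvmax_over_min_suvmax"]), 1.0)
  expect_equal(unname(one["max_suvmax_minus_min_suvmean"]), 2.0)
  expect_equal(unname(one["max_of_suvmax_minus_suvmean"]), 2.0)
})

test_that("heterogeneity indices: identical lesions 0, pair count, max >= mean", {
  tab3 <- rbind(lesion_row(1, 1, "liver", 2, 5, 7),
                lesion_row(1, 2, "bone", 1, 3, 4),
                lesion_row(1, 3, "node", 4, 9, 12))
  h <- suppressWarnings(compute_heterogeneity_indices(tab3))
  expect_gte(h[["maximal_tumor_divergence"]],
             h[["average_tumoral_heterogeneity"]])
  expect_gte(h[["average_tumoral_heterogeneity"]], 0)

  same <- rbind(lesion_row(1, 1, "liver", 2, 5, 7),
                lesion_row(1, 2, "liver", 2, 5, 7))
  hs <- suppressWarnings(compute_heterogeneity_indices(same))
  expect_equal(unname(hs), c(0, 0), tolerance = 1e-12)

  h1 <- compute_heterogeneity_indices(tab3[1, ])
  expect_true(all(is.na(h1)))
})

test_that("orthogonal scaled vectors give dissimilarity 1 for both indices", {
  # two lesions, two informative features; cohort min-max sends them to
  # (1, 0) and (0, 1)
  tab <- rbind(lesion_row(1, 1, "liver", 2, 5, 5.5),
               lesion_row(1, 2, "bone", 1, 9, 9.5))
  sc <- suppressWarnings(
    ssthet:::heterogeneity_scaling(tab, c("volume_ml", "suv_mean"), "minmax"))
  h <- compute_heterogeneity_indices(tab, scaling_stats = sc)
  expect_equal(unname(h), c(1, 1), tolerance = 1e-12)
})

test_that("liver dominance uses the majority-volume rule", {
  mk <- function(liver_ml, other_ml) {
    rbind(lesion_row(1, 1, "liver", liver_ml, 5, 6),
          lesion_row(1, 2, "bone", other_ml, 5, 6))
  }
  expect_true(liver_dominance(mk(60, 40)))
  expect_false(liver_dominance(mk(40, 60)))
  expect_false(liver_dominance(lesion_row(1, 1, "node", 10, 5, 6)))
  expect_false(liver_dominance(NULL))
})

test_that("patient record carries exactly 53 quantitative features", {
  tab <- rbind(lesion_row(1, 1, "liver", 2, 5, 7),
               lesion_row(1, 2, "bone", 1, 3, 4),
               lesion_row(1, 3, "node", 0.2, 9, 12))
  flt <- apply_volume_filter(tab)
  rec <- suppressWarnings(
    build_patient_record(flt$all, flt$eligible, liver_reference(4, 5)))
  expect_true(all(patient_feature_names() %in% names(rec)))
  expect_equal(length(patient_feature_names()), 53)
  expect_equal(rec$n_lesions, 3)
  expect_equal(rec$n_eligible_lesions, 2)

  # single eligible lesion: SDs and heterogeneity missing, means present
  rec1 <- suppressWarnings(
    build_patient_record(tab[c(1, 3), ], tab[1, , drop = FALSE],
                         liver_reference(4, 5)))
  expect_true(is.na(rec1$sd_suv_mean))
  expect_true(is.na(rec1$average_tumoral_heterogeneity))
  expect_false(is.na(rec1$mean_suv_mean))
})

test_that("patient summaries are permutation-invariant and match brute force", {
  set.seed(31)
  liver <- liver_reference(5, 6.5)
  segs <- lapply(1:6, function(k) random_segment(k, pid = 1L,
                                                 vox_ml = 0.15))
  tab <- lesion_feature_table(segs, liver)
  flt <- apply_volume_filter(tab)
  rec <- suppressWarnings(compute_patient_features(
    tab, list("1" = liver)))
  perm <- tab[sample(nrow(tab)), ]
  rec_p <- suppressWarnings(compute_patient_features(
    perm, list("1" = liver)))
  for (f in patient_feature_names())
    expect_equal(rec[[f]], rec_p[[f]], tolerance = 1e-12, label = f)

  # brute-force check of a few reductions from the raw table
  eli <- flt$eligible
  expect_equal(rec$mean_cv_suv, sum(eli$cv_suv) / nrow(eli),
               tolerance = 1e-12)
  expect_equal(rec$max_kurtosis, max(eli$kurtosis), tolerance = 1e-12)
  expect_equal(rec$total_volume_ml, sum(tab$volume_ml), tolerance = 1e-12)
  expect_equal(rec$max_suvmax_over_min_suvmax,
               max(eli$suv_max) / min(eli$suv_max), tolerance = 1e-12)
})

test_that("pairwise dissimilarities under min-max scaling stay in [0, 1]", {
  set.seed(41)
  liver <- liver_reference(5, 6.5)
  tab <- lesion_feature_table(
    lapply(1:40, function(k) random_segment(k, pid = (k %% 8) + 1,
                                            vox_ml = 0.2)), liver)
  sc <- suppressWarnings(ssthet:::heterogeneity_scaling(tab))
  vec <- ssthet:::scale_lesion_vectors(tab, sc)
  vec <- vec[complete.cases(vec), ]
  expect_true(all(vec >= -1e-12 & vec <= 1 + 1e-12))
  n <- nrow(vec)
  for (k in 1:200) {
    ij <- sample(n, 2)
    d <- suppressWarnings(cosine_dissimilarity(vec[ij[1], ], vec[ij[2], ]))
    if (!is.na(d)) expect_true(d >= -1e-12 && d <= 1 + 1e-12)
  }
})
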
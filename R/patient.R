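#' Names of the 53 patient-level quantitative imaging features
#'
#' The patient-level predictor set: each of the 14 intra-lesional indices
#' summarized by mean / max / SD across eligible lesions (42), the four
#' whole-body totals, the three SUV spread indices, the two
#' cosine-dissimilarity heterogeneity indices, and the two liver reference
#' statistics.
#' @return Character vector of length 53.
#' @export
patient_feature_names <- function() {
  base <- intralesional_feature_names()
  c(paste0("mean_", base), paste0("max_", base), paste0("sd_", base),
    "total_volume_ml", "n_lesions", "total_receptor_expression",
    "total_liver_corrected_expression",
    "max_suvmax_over_min_suvmax", "max_suvmax_minus_min_suvmean",
    "max_of_suvmax_minus_suvmean",
    "average_tumoral_heterogeneity", "maximal_tumor_divergence",
    "liver_suv_mean", "liver_suv_max")
}

#' Pairwise cosine dissimilarity
#'
#' `1 - (u . v) / (||u|| ||v||)`. Returns `NA` with a warning when either
#' vector is all zero.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar dissimilarity.
#' @export
cosine_dissimilarity <- function(u, v) {
  if (length(u) != length(v) || !length(u))
    stopf("vectors must have equal positive length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warnf("zero vector in cosine dissimilarity")
    return(NA_real_)
  }
  1 - sum(u * v) / (nu * nv)
}

#' Mean / max / SD summaries of the intra-lesional indices
#'
#' Summarizes each of the 14 intra-lesional indices across a patient's
#' eligible lesions with the arithmetic mean, the maximum, and the sample SD
#' (divisor n-1). Missing lesion values (e.g. skewness of a flat lesion) are
#' excluded pairwise; the effective n per index is recorded in the
#' `"n_used"` attribute. With fewer than 2 contributing lesions the SD is
#' missing; with none, all three are missing.
#'
#' @param eligible Eligible rows of a lesion feature table.
#' @return Named numeric vector of length 42 (with attribute `n_used`).
#' @export
summarize_intralesional <- function(eligible) {
  base <- intralesional_feature_names()
  out <- setNames(rep(NA_real_, 3 * length(base)),
                  c(paste0("mean_", base), paste0("max_", base),
                    paste0("sd_", base)))
  n_used <- setNames(integer(length(base)), base)
  if (is.null(eligible) || !nrow(eligible)) {
    warnf("no eligible lesions: all intra-lesional summaries missing")
    attr(out, "n_used") <- n_used
    return(out)
  }
  for (f in base) {
    x <- eligible[[f]]
    x <- x[!is.na(x)]
    n_used[f] <- length(x)
    if (!length(x)) next
    out[paste0("mean_", f)] <- mean(x)
    out[paste0("max_", f)] <- max(x)
    out[paste0("sd_", f)] <- if (length(x) >= 2) stats::sd(x) else NA_real_
  }
  attr(out, "n_used") <- n_used
  out
}

#' Whole-body totals
#'
#' Total volume and lesion count are taken over all lesions regardless of
#' the volume filter; the receptor-expression totals are summed over
#' eligible lesions only.
#'
#' @param all_lesions,eligible Lesion feature table rows.
#' @return Named numeric vector of length 4.
#' @export
compute_totals <- function(all_lesions, eligible) {
  nr <- function(df) if (is.null(df)) 0L else nrow(df)
  c(total_volume_ml = if (nr(all_lesions)) sum(all_lesions$volume_ml) else 0,
    n_lesions = nr(all_lesions),
    total_receptor_expression =
      if (nr(eligible)) sum(eligible$receptor_expression) else 0,
    total_liver_corrected_expression =
      if (nr(eligible)) sum(eligible$liver_corrected_receptor_expression) else 0)
}

#' SUV spread indices across lesions
#'
#' `max SUVmax / min SUVmax`, `max SUVmax - min SUVmean` (extrema taken
#' independently across eligible lesions) and `max(SUVmax - SUVmean)` (the
#' per-lesion difference maximized over lesions).
#'
#' @param eligible Eligible rows of a lesion feature table (>= 1 row).
#' @return Named numeric vector of length 3.
#' @export
compute_spread_indices <- function(eligible) {
  if (is.null(eligible) || !nrow(eligible))
    return(c(max_suvmax_over_min_suvmax = NA_real_,
             max_suvmax_minus_min_suvmean = NA_real_,
             max_of_suvmax_minus_suvmean = NA_real_))
  min_max <- min(eligible$suv_max)
  ratio <- if (min_max > 0) max(eligible$suv_max) / min_max else {
    warnf("min SUVmax is 0: spread ratio missing")
    NA_real_
  }
  c(max_suvmax_over_min_suvmax = ratio,
    max_suvmax_minus_min_suvmean = max(eligible$suv_max) - min(eligible$suv_mean),
    max_of_suvmax_minus_suvmean = max(eligible$suv_max - eligible$suv_mean))
}

# Cohort-wide scaling statistics for the heterogeneity feature vectors.
heterogeneity_scaling <- function(cohort_eligible,
                                  feature_names = intralesional_feature_names(),
                                  scaling = c("minmax", "zscore", "none")) {
  scaling <- match.arg(scaling)
  stats <- lapply(feature_names, function(f) {
    x <- cohort_eligible[[f]]
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    switch(scaling,
           minmax = c(lo = min(x), hi = max(x)),
           zscore = c(mu = mean(x), s = stats::sd(x)),
           none = c(0, 1))
  })
  names(stats) <- feature_names
  constant <- vapply(feature_names, function(f) {
    st <- stats[[f]]
    is.null(st) || (scaling == "minmax" && st["hi"] == st["lo"]) ||
      (scaling == "zscore" && (!is.finite(st["s"]) || st["s"] == 0))
  }, logical(1))
  if (any(constant))
    warnf("dropping constant feature(s) from heterogeneity vectors: %s",
          paste(feature_names[constant], collapse = ", "))
  list(scaling = scaling, stats = stats[!constant],
       features = feature_names[!constant])
}

scale_lesion_vectors <- function(lesions, sc) {
  m <- sapply(sc$features, function(f) {
    x <- lesions[[f]]
    st <- sc$stats[[f]]
    switch(sc$scaling,
           minmax = (x - st[["lo"]]) / (st[["hi"]] - st[["lo"]]),
           zscore = (x - st[["mu"]]) / st[["s"]],
           none = x)
  })
  matrix(m, nrow = nrow(lesions),
         dimnames = list(NULL, sc$features))
}

#' Inter-lesional heterogeneity indices
#'
#' Builds one feature vector per eligible lesion (default: the 14
#' intra-lesional indices), scales each feature across the cohort's eligible
#' lesions (min-max to `[0, 1]` by default, keeping components nonnegative so
#' every pairwise dissimilarity lies in `[0, 1]`), computes all
#' `n (n - 1) / 2` pairwise cosine dissimilarities within the patient, and
#' returns their average (average tumoral heterogeneity) and maximum
#' (maximal tumor divergence). Both are missing with fewer than 2 eligible
#' lesions with complete vectors.
#'
#' @param eligible Eligible lesion rows for one patient.
#' @param feature_names Features forming the lesion vector.
#' @param scaling `"minmax"` (default), `"zscore"` or `"none"`.
#' @param scaling_stats Optional precomputed cohort scaling (from the
#'   internal cohort pass); when `NULL`, scaling is computed from `eligible`.
#' @return Named numeric vector: `average_tumoral_heterogeneity`,
#'   `maximal_tumor_divergence`.
#' @export
compute_heterogeneity_indices <- function(eligible,
                                          feature_names = intralesional_feature_names(),
                                          scaling = "minmax",
                                          scaling_stats = NULL) {
  out <- c(average_tumoral_heterogeneity = NA_real_,
           maximal_tumor_divergence = NA_real_)
  if (is.null(eligible) || nrow(eligible) < 2) return(out)
  sc <- scaling_stats %||%
    heterogeneity_scaling(eligible, feature_names, scaling)
  if (!length(sc$features)) {
    # every feature constant across these lesions: identical vectors, so
    # fall back to unscaled vectors (dissimilarity 0 unless degenerate)
    sc <- list(scaling = "none", features = feature_names,
               stats = setNames(rep(list(c(0, 1)), length(feature_names)),
                                feature_names))
  }
  vec <- scale_lesion_vectors(eligible, sc)
  complete <- stats::complete.cases(vec)
  vec <- vec[complete, , drop = FALSE]
  if (nrow(vec) < 2) return(out)
  n <- nrow(vec)
  diss <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diss <- c(diss, suppressWarnings(cosine_dissimilarity(vec[i, ], vec[j, ])))
  }
  if (all(is.na(diss))) return(out)
  if (any(is.na(diss))) warnf("zero-vector lesion(s) excluded from heterogeneity")
  c(average_tumoral_heterogeneity = mean(diss, na.rm = TRUE),
    maximal_tumor_divergence = max(diss, na.rm = TRUE))
}

#' Liver-dominant disease flag
#'
#' A patient is liver-dominant when hepatic lesions make up more than
#' `threshold` (default 50%) of the total lesion volume, over all lesions
#' regardless of the eligibility filter.
#'
#' @param all_lesions Lesion feature table rows (needs `organ_label`,
#'   `volume_ml`).
#' @param threshold Fraction of total volume (default 0.5).
#' @return Logical flag.
#' @export
liver_dominance <- function(all_lesions, threshold = 0.5) {
  if (is.null(all_lesions) || !nrow(all_lesions)) return(FALSE)
  total <- sum(all_lesions$volume_ml)
  liver <- sum(all_lesions$volume_ml[all_lesions$organ_label == "liver"],
               na.rm = TRUE)
  total > 0 && liver > threshold * total
}

#' Assemble one patient's feature record
#'
#' Combines the 42 intra-lesional summaries, 4 totals, 3 spread indices,
#' 2 heterogeneity indices and the 2 liver reference statistics into the 53
#' quantitative imaging features, plus the liver-dominance flag and lesion
#' counts. Missing values propagate; nothing is imputed.
#'
#' @param all_lesions All lesion rows for the patient.
#' @param eligible Volume-eligible lesion rows for the patient.
#' @param liver A `liver_reference`.
#' @param patient_id Identifier for the output row.
#' @param het_scaling Optional precomputed cohort scaling statistics.
#' @param liver_dominance_threshold See [liver_dominance()].
#' @return One-row data frame: `patient_id`, the 53 features,
#'   `liver_dominant`, `n_eligible_lesions`.
#' @export
build_patient_record <- function(all_lesions, eligible, liver,
                                 patient_id = NULL, het_scaling = NULL,
                                 liver_dominance_threshold = 0.5) {
  patient_id <- patient_id %||%
    (if (!is.null(all_lesions) && nrow(all_lesions))
      all_lesions$patient_id[1] else NA)
  sums <- summarize_intralesional(eligible)
  tot <- compute_totals(all_lesions, eligible)
  spread <- compute_spread_indices(eligible)
  het <- compute_heterogeneity_indices(eligible, scaling_stats = het_scaling)
  rec <- data.frame(patient_id = patient_id, t(sums), t(tot), t(spread),
                    t(het),
                    liver_suv_mean = liver$liver_suv_mean,
                    liver_suv_max = liver$liver_suv_max,
                    stringsAsFactors = FALSE)
  rec$liver_dominant <- liver_dominance(all_lesions,
                                        liver_dominance_threshold)
  rec$n_eligible_lesions <- if (is.null(eligible)) 0L else nrow(eligible)
  rec
}

#' Patient feature table for a whole cohort
#'
#' Applies the volume filter, computes cohort-wide heterogeneity scaling
#' over all eligible lesions, and assembles one [build_patient_record()] row
#' per patient.
#'
#' @param lesion_table Lesion feature table for the cohort (all lesions).
#' @param liver_refs Named list of `liver_reference` objects, one per
#'   patient id.
#' @param threshold_cc Volume filter threshold.
#' @param het_features,het_scaling Heterogeneity vector composition/scaling.
#' @param liver_dominance_threshold See [liver_dominance()].
#' @return Data frame, one row per patient, with a `meta` attribute recording
#'   the conventions in force.
#' @export
compute_patient_features <- function(lesion_table, liver_refs,
                                     threshold_cc = VOLUME_FILTER_CC,
                                     het_features = intralesional_feature_names(),
                                     het_scaling = "minmax",
                                     liver_dominance_threshold = 0.5) {
  flt <- apply_volume_filter(lesion_table, threshold_cc)
  sc <- if (nrow(flt$eligible)) {
    heterogeneity_scaling(flt$eligible, het_features, het_scaling)
  } else NULL
  ids <- unique(lesion_table$patient_id)
  rows <- lapply(ids, function(pid) {
    all_p <- lesion_table[lesion_table$patient_id == pid, , drop = FALSE]
    eli_p <- flt$eligible[flt$eligible$patient_id == pid, , drop = FALSE]
    liver <- liver_refs[[as.character(pid)]]
    if (is.null(liver)) stopf("no liver reference for patient '%s'", pid)
    build_patient_record(all_p, eli_p, liver, patient_id = pid,
                         het_scaling = sc,
                         liver_dominance_threshold = liver_dominance_threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(
    volume_filter_cc = threshold_cc,
    heterogeneity_features = het_features,
    heterogeneity_scaling = het_scaling,
    liver_dominance_threshold = liver_dominance_threshold,
    n_quantitative_features = length(patient_feature_names()))
  out
}
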
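#' Names of the 14 intra-lesional heterogeneity indices
#'
#' First-order intensity-histogram statistics of a lesion's voxel SUV
#' distribution plus the volume, receptor-expression and liver-corrected
#' ratios computed from them.
#' @return Character vector of length 14.
#' @export
intralesional_feature_names <- function() {
  c("volume_ml", "suv_mean", "suv_max", "sd_suv", "skewness", "kurtosis",
    "cv_suv", "max_over_mean", "excess_over_mean", "receptor_expression",
    "liver_corrected_receptor_expression", "liver_corrected_suv_mean",
    "liver_corrected_suv_max", "liver_corrected_suv_max_lmean")
}

#' Minimum metabolic volume for feature eligibility (cc)
#'
#' Lesions below this volume (that of a 1 cm-diameter sphere) are excluded
#' from all indices except the whole-body totals and the lesion count, to
#' avoid the partial-volume effect near scanner resolution.
#' @export
VOLUME_FILTER_CC <- 0.524

#' First-order intensity histogram statistics
#'
#' Computes mean, maximum, standard deviation, skewness, excess kurtosis and
#' coefficient of variation of a set of voxel SUVs. The SD uses the
#' population convention (divisor n) by default; skewness is
#' `m3 / m2^(3/2)` and kurtosis `m4 / m2^2 - 3` with `mj` the central sample
#' moments. Skewness and kurtosis are reported as missing for degenerate
#' samples (`n < 3` or zero variance), not as zero.
#'
#' @param suv Numeric vector of finite, nonnegative SUVs (length >= 1).
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @param kurtosis_excess If `TRUE` (default) subtract 3 so a Gaussian scores 0.
#' @return Named list: `mean`, `max`, `sd`, `skewness`, `kurtosis`, `cv`.
#' @export
compute_histogram_stats <- function(suv, sd_divisor = c("n", "n-1"),
                                    kurtosis_excess = TRUE) {
  sd_divisor <- match.arg(sd_divisor)
  if (!length(suv)) stopf("empty SUV list")
  if (any(!is.finite(suv))) stopf("SUV values must be finite")
  if (any(suv < 0)) stopf("SUV values must be nonnegative")
  n <- length(suv)
  m <- mean(suv)
  ctr <- suv - m
  m2 <- mean(ctr^2); m3 <- mean(ctr^3); m4 <- mean(ctr^4)
  s <- if (sd_divisor == "n") sqrt(m2) else {
    if (n > 1) sqrt(sum(ctr^2) / (n - 1)) else 0
  }
  skew <- if (m2 > 0 && n >= 3) m3 / m2^1.5 else NA_real_
  kurt <- if (m2 > 0 && n >= 3) m4 / m2^2 - (if (kurtosis_excess) 3 else 0)
          else NA_real_
  cv <- if (m > 0) s / m else NA_real_
  list(mean = m, max = max(suv), sd = s, skewness = skew, kurtosis = kurt,
       cv = cv)
}

#' Intra-lesional feature record
#'
#' Populates the 14 intra-lesional indices for one lesion segment: the
#' histogram statistics of its voxel SUVs, the metabolic volume, the
#' receptor-expression products (volume x SUVmean) and the liver-corrected
#' ratios, plus the volume-eligibility flag.
#'
#' @param seg A `lesion_segment`.
#' @param liver A `liver_reference` with `liver_suv_mean > 0`.
#' @param threshold_cc Eligibility threshold ([VOLUME_FILTER_CC]).
#' @param sd_divisor,kurtosis_excess Histogram conventions, see
#'   [compute_histogram_stats()].
#' @return One-row data frame.
#' @export
compute_intralesional_features <- function(seg, liver,
                                           threshold_cc = VOLUME_FILTER_CC,
                                           sd_divisor = "n",
                                           kurtosis_excess = TRUE) {
  stopifnot(inherits(seg, "lesion_segment"))
  if (!length(seg$suv)) stopf("empty lesion segment")
  if (!is.finite(liver$liver_suv_mean) || liver$liver_suv_mean <= 0)
    stopf("liver SUVmean must be > 0")
  h <- compute_histogram_stats(seg$suv, sd_divisor = sd_divisor,
                               kurtosis_excess = kurtosis_excess)
  v <- seg$volume_ml
  data.frame(
    lesion_id = seg$lesion_id,
    patient_id = seg$patient_id,
    organ_label = seg$organ_label,
    volume_ml = v,
    suv_mean = h$mean,
    suv_max = h$max,
    sd_suv = h$sd,
    skewness = h$skewness,
    kurtosis = h$kurtosis,
    cv_suv = h$cv,
    max_over_mean = if (h$mean > 0) h$max / h$mean else NA_real_,
    excess_over_mean = if (h$mean > 0) (h$max - h$mean) / h$mean else NA_real_,
    receptor_expression = v * h$mean,
    liver_corrected_receptor_expression = v * h$mean / liver$liver_suv_mean,
    liver_corrected_suv_mean = h$mean / liver$liver_suv_mean,
    liver_corrected_suv_max = h$max / liver$liver_suv_max,
    liver_corrected_suv_max_lmean = h$max / liver$liver_suv_mean,
    eligible = v >= threshold_cc,
    stringsAsFactors = FALSE
  )
}

#' Lesion feature table for a list of segments
#'
#' @param segments List of `lesion_segment` objects.
#' @param liver A `liver_reference`.
#' @param ... Passed to [compute_intralesional_features()].
#' @return Data frame with one row per lesion.
#' @export
lesion_feature_table <- function(segments, liver, ...) {
  do.call(rbind, lapply(segments, compute_intralesional_features,
                        liver = liver, ...))
}

#' Apply the metabolic-volume eligibility filter
#'
#' Lesions with volume below the threshold are excluded from all indices
#' except whole-body total volume and lesion count; the full record set is
#' retained for those totals. The boundary is closed: a lesion exactly at the
#' threshold is eligible ("less than" excluded).
#'
#' @param records Lesion feature table ([lesion_feature_table()]).
#' @param threshold_cc Volume threshold in cc.
#' @return List with `eligible` (filtered rows) and `all` (unchanged input).
#' @export
apply_volume_filter <- function(records, threshold_cc = VOLUME_FILTER_CC) {
  if (is.null(records) || !nrow(records))
    return(list(eligible = records, all = records))
  list(eligible = records[records$volume_ml >= threshold_cc, , drop = FALSE],
       all = records)
}
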
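#' Uno's censoring-robust C-statistic
#'
#' Inverse-probability-of-censoring-weighted (IPCW) concordance. Over ordered
#' pairs `(i, j)` with `event_i = 1`, `T_i < T_j` and `T_i < tau`, each pair
#' is weighted by `1 / G(T_i-)^2` where `G` is the Kaplan-Meier estimator of
#' the censoring distribution; the numerator adds the weight for a concordant
#' pair (`score_i > score_j`; higher score = higher risk) and half the weight
#' for a score tie. The standard error is a leave-one-subject-out jackknife
#' over the weighted pair sums, and the reported p-value tests the null
#' C = 0.50 (chance discrimination) with a two-sided normal test.
#'
#' @param time Observed times (months).
#' @param event Event indicators (0/1).
#' @param score Risk scores (higher = higher risk), finite.
#' @param tau Truncation time; pairs with `T_i >= tau` are excluded. Must not
#'   exceed the largest observed time.
#' @param se Compute the jackknife standard error (default `TRUE`).
#' @return List: `c`, `se`, `p_value` (vs 0.50), `n_pairs` (weighted
#'   denominator), `tau`.
#' @export
uno_c <- function(time, event, score, tau = max(time), se = TRUE) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  if (any(!is.finite(score))) stopf("risk scores must be finite")
  if (tau > max(time)) stopf("tau exceeds the largest observed time")
  g <- censoring_survival_left(time, event, time)
  contrib <- event == 1 & time < tau
  if (any(contrib & g <= 0))
    stopf("censoring survival is 0 at a contributing event time; tau too large")
  ginv2 <- ifelse(g > 0, 1 / g^2, 0)
  res <- cpp_uno_c(as.numeric(time), as.integer(event), as.numeric(score),
                   ginv2, tau, se)
  p <- if (se && is.finite(res$se) && res$se > 0)
    2 * pnorm(-abs(res$c - 0.5) / res$se) else NA_real_
  list(c = res$c, se = res$se, p_value = p, n_pairs = res$den, tau = tau)
}

# Concordance of each column of a score matrix under shared weights; used by
# the cross-validated lambda search.
uno_c_multi <- function(time, event, scores, tau) {
  g <- censoring_survival_left(time, event, time)
  ginv2 <- ifelse(g > 0, 1 / g^2, 0)
  cpp_uno_c_multi(as.numeric(time), as.integer(event),
                  as.matrix(scores), ginv2, tau)
}

#' Harrell's concordance (unweighted)
#'
#' The unweighted analogue of [uno_c()] over the same pair set; equal to
#' Uno's C when there is no censoring.
#' @inheritParams uno_c
#' @return Scalar concordance.
#' @export
harrell_c <- function(time, event, score, tau = max(time)) {
  res <- cpp_uno_c(as.numeric(time), as.integer(event), as.numeric(score),
                   rep(1, length(time)), tau, FALSE)
  res$c
}
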
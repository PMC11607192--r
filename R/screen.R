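#' Univariable Cox screening with Uno's C
#'
#' Fits one unpenalized Cox model per feature (via [survival::coxph()],
#' Efron ties), reporting the hazard ratio per unit with its Wald 95% CI and
#' p-value, the direction of the hazard association (`"+"` when increasing
#' values shorten survival, i.e. HR > 1), and Uno's C-statistic of the
#' feature's linear predictor with the two-sided p-value against the chance
#' value 0.50. Each feature uses its own complete cases (n reported);
#' per-feature failures (e.g. constant features) yield missing rows with a
#' warning rather than aborting the screen.
#'
#' @param features Data frame of candidate predictors (numeric columns).
#' @param time,event Survival outcome.
#' @param tau Truncation time for Uno's C.
#' @param conf_level Wald CI level.
#' @return Data frame with one row per feature: `feature`, `n`, `n_events`,
#'   `hr`, `hr_ci_low`, `hr_ci_high`, `hr_direction`, `c_statistic`,
#'   `c_se`, `p_value_c_vs_half`, `p_value_wald`.
#' @export
univariable_screen <- function(features, time, event, tau = max(time),
                               conf_level = 0.95) {
  stopifnot(is.data.frame(features), nrow(features) == length(time))
  if (!ncol(features)) stopf("no features to screen")
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(names(features), function(f) {
    na_row <- data.frame(feature = f, n = NA_integer_, n_events = NA_integer_,
                         hr = NA_real_, hr_ci_low = NA_real_,
                         hr_ci_high = NA_real_, hr_direction = NA_character_,
                         c_statistic = NA_real_, c_se = NA_real_,
                         p_value_c_vs_half = NA_real_, p_value_wald = NA_real_,
                         stringsAsFactors = FALSE)
    x <- features[[f]]
    if (!is.numeric(x)) return(na_row)
    ok <- !is.na(x) & is.finite(time) & !is.na(event)
    xs <- x[ok]; ts <- time[ok]; ev <- event[ok]
    if (length(unique(xs)) < 2 || sum(ev) < 1) {
      warnf("feature '%s' skipped (constant or no events)", f)
      return(na_row)
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(ts, ev) ~ xs),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(survival::Surv(ts, ev) ~ xs))
      })
    if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
      warnf("feature '%s' failed to fit", f)
      return(na_row)
    }
    b <- stats::coef(fit)[1]
    se <- sqrt(stats::vcov(fit)[1, 1])
    cc <- tryCatch(
      uno_c(ts, ev, as.numeric(xs * b), tau = min(tau, max(ts))),
      error = function(e) list(c = NA_real_, se = NA_real_, p_value = NA_real_))
    data.frame(feature = f, n = length(xs), n_events = sum(ev),
               hr = exp(b), hr_ci_low = exp(b - z * se),
               hr_ci_high = exp(b + z * se),
               hr_direction = if (b > 0) "+" else "-",
               c_statistic = cc$c, c_se = cc$se,
               p_value_c_vs_half = cc$p_value,
               p_value_wald = 2 * pnorm(-abs(b / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
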
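#' Kaplan-Meier estimate with pointwise confidence intervals
#'
#' Product-limit estimator with Greenwood variance and pointwise 95%
#' confidence intervals on the log(-log) scale, via [survival::survfit()].
#' Subjects censored at an event time are counted at risk at that time.
#'
#' @param time Observed times in months (> 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @return A `km_curve` data frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `lower`, `upper`, with the fitted `survfit` object attached as
#'   attribute `fit`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (!length(time)) stopf("no records")
  if (any(time <= 0)) stopf("all times must be positive")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, lower = fit$lower, upper = fit$upper)
  # survfit leaves the CI undefined while S(t) = 1; degenerate at 1 there
  deg <- out$surv == 1 & is.na(out$lower)
  out$lower[deg] <- 1; out$upper[deg] <- 1
  class(out) <- c("km_curve", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Survival probability at given times from a km_curve
#' @param curve A `km_curve`.
#' @param times Times (months) at which to read off the step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    idx <- which(curve$time <= t)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

# Censoring-distribution Kaplan-Meier, evaluated with left limits G(t-);
# the inverse-probability-of-censoring weight at an event time t is 1/G(t-)^2.
censoring_survival_left <- function(time, event, eval_times) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  idx <- findInterval(eval_times, fit$time, left.open = TRUE)
  c(1, fit$surv)[idx + 1]
}
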
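#' Survival simulation specification
#'
#' Defines a proportional-hazards generator over patient-level features:
#' event times are drawn with hazard `baseline_hazard * exp(beta' z)` where
#' `z` are the named features standardized across the cohort (so each
#' coefficient is a log hazard ratio per SD), censoring is uniform on
#' `(0, censoring_max)`, and an optional administrative truncation caps the
#' observation window (24 months for the time-to-progression endpoint).
#'
#' @param true_coefficients Named numeric vector: feature -> log-HR per SD.
#'   May be empty (pure noise outcome).
#' @param baseline_hazard Events per month (> 0).
#' @param censoring_max Upper bound of the uniform censoring time (months).
#' @param admin_truncation_months Administrative truncation (months), or
#'   `NULL` for none (overall survival).
#' @param shape Weibull shape of the event-time distribution; 1 (default)
#'   gives the exponential / constant-hazard model.
#' @param endpoint Label stored in the output (`"TTP24"` or `"OS"`).
#' @return A `survival_sim_spec` list.
#' @export
survival_sim_spec <- function(true_coefficients = numeric(),
                              baseline_hazard = 0.03,
                              censoring_max = 36,
                              admin_truncation_months = NULL,
                              shape = 1,
                              endpoint = c("TTP24", "OS")) {
  endpoint <- match.arg(endpoint)
  assert_scalar_num(baseline_hazard, "baseline_hazard", lower = 0, strict = TRUE)
  assert_scalar_num(censoring_max, "censoring_max", lower = 0, strict = TRUE)
  assert_scalar_num(shape, "shape", lower = 0, strict = TRUE)
  if (length(true_coefficients) &&
      (is.null(names(true_coefficients)) || any(names(true_coefficients) == "")))
    stopf("'true_coefficients' must be a named vector")
  if (!is.null(admin_truncation_months))
    assert_scalar_num(admin_truncation_months, "admin_truncation_months",
                      lower = 0, strict = TRUE)
  structure(list(true_coefficients = true_coefficients,
                 baseline_hazard = baseline_hazard,
                 censoring_max = censoring_max,
                 admin_truncation_months = admin_truncation_months,
                 shape = shape, endpoint = endpoint),
            class = "survival_sim_spec")
}

#' Simulate survival records from patient-level features
#'
#' Draws one survival record per row of `features` under the
#' proportional-hazards model of a [survival_sim_spec()]. Features named in
#' the specification's `true_coefficients` are z-scored across the supplied
#' cohort before the linear predictor is formed. The observed time is the
#' minimum of event, censoring, and administrative-truncation times and the
#' event flag is 1 iff the event time attains that minimum.
#'
#' @param features Data frame of patient-level features; a `patient_id`
#'   column is carried through when present.
#' @param spec A [survival_sim_spec()].
#' @param seed Integer seed; records are deterministic given
#'   `(features, spec, seed)`.
#' @return Data frame: `patient_id`, `endpoint`, `time_months`, `event`.
#' @export
simulate_survival <- function(features, spec, seed = 1L) {
  stopifnot(inherits(spec, "survival_sim_spec"), is.data.frame(features))
  n <- nrow(features)
  if (n < 2L) stopf("need at least 2 patients")
  lp <- rep(0, n)
  for (nm in names(spec$true_coefficients)) {
    if (!nm %in% names(features)) stopf("feature '%s' not found", nm)
    x <- features[[nm]]
    if (all(is.na(x))) stopf("feature '%s' is entirely missing", nm)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stopf("feature '%s' has no spread", nm)
    z <- (x - mean(x, na.rm = TRUE)) / s
    z[is.na(z)] <- 0
    lp <- lp + spec$true_coefficients[[nm]] * z
  }
  with_seed(seed, {
    rate <- spec$baseline_hazard * exp(lp)
    u <- runif(n)
    t_event <- (-log(u) / rate)^(1 / spec$shape)
    t_cens <- runif(n, 0, spec$censoring_max)
    t_admin <- spec$admin_truncation_months %||% Inf
    obs <- pmin(t_event, t_cens, t_admin)
    event <- as.integer(t_event <= t_cens & t_event <= t_admin)
    data.frame(
      patient_id = features$patient_id %||% seq_len(n),
      endpoint = spec$endpoint,
      time_months = obs,
      event = event
    )
  })
}
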
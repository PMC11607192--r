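#' Bootstrap optimism-corrected concordance
#'
#' Harrell's bootstrap optimism correction for the penalized Cox model at a
#' fixed selected penalty: for each bootstrap resample, the model is refitted
#' (at `lambda_star`, or with full lambda re-selection when
#' `refit_lambda = TRUE`) and the optimism of that resample is the difference
#' between its apparent concordance (bootstrap model on the bootstrap
#' sample) and its test concordance (bootstrap model scored on the original
#' data), both Uno's C. The corrected C is the apparent C of the full-data
#' model minus the mean optimism. The 95% CI is the percentile interval of
#' the optimism-shifted bootstrap distribution `{apparent C - optimism_b}`
#' (`ci_type = "percentile"`, default) or a normal approximation. A model
#' whose CI excludes 0.50 predicts better than chance.
#'
#' Resamples with fewer than 2 events are redrawn (counted; a warning is
#' issued when more than 10% of draws are redraws).
#'
#' @param X Feature matrix.
#' @param time,event Survival outcome.
#' @param lambda_star Selected penalty.
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param tau Truncation time for Uno's C.
#' @param seed Integer seed.
#' @param ties Tie handling.
#' @param refit_lambda Re-run [select_lambda_cv()] inside each resample
#'   (expensive; off by default).
#' @param cv_args List of arguments for the inner lambda re-selection.
#' @param ci_type `"percentile"` or `"normal"`.
#' @param resample `"bootstrap"` (default) or `"identity"`, a diagnostic
#'   mode in which every resample is the original data (optimism is then
#'   exactly zero).
#' @return A `multivariable_model` list: `selected_features`,
#'   `coefficients`, `lambda`, `apparent_c`, `corrected_c`, `ci`,
#'   `better_than_chance`, `optimism`, `n_bootstrap`, `n_redraws`, `seed`.
#' @export
optimism_corrected_c <- function(X, time, event, lambda_star,
                                 n_bootstrap = 1000, tau = max(time),
                                 seed = 1L, ties = "efron",
                                 refit_lambda = FALSE, cv_args = list(),
                                 ci_type = c("percentile", "normal"),
                                 resample = c("bootstrap", "identity")) {
  ci_type <- match.arg(ci_type)
  resample <- match.arg(resample)
  X <- as.matrix(X)
  n <- nrow(X)
  full <- fit_cox(X, time, event, lambda = lambda_star, ties = ties,
                  strict = FALSE)
  beta_full <- ifelse(is.na(full$beta[, 1]), 0, full$beta[, 1])
  eta_full <- as.numeric(X %*% beta_full)
  apparent <- uno_c(time, event, eta_full, tau = tau, se = FALSE)$c
  if (is.na(apparent)) stopf("apparent concordance undefined")

  optimism <- numeric(n_bootstrap)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- NULL
      if (resample == "identity") idx <- seq_len(n) else {
        for (attempt in 1:100) {
          cand <- sample.int(n, n, replace = TRUE)
          if (sum(event[cand]) >= 2) { idx <- cand; break }
          n_redraws <- n_redraws + 1L
        }
        if (is.null(idx)) stopf("could not draw a bootstrap sample with >= 2 events")
      }
      Xb <- X[idx, , drop = FALSE]; tb <- time[idx]; eb <- event[idx]
      lam_b <- lambda_star
      if (refit_lambda) {
        cva <- utils::modifyList(
          list(X = Xb, time = tb, event = eb, tau = tau,
               seed = derive_seed(seed, paste0("cv", b)), ties = ties),
          cv_args)
        lam_b <- do.call(select_lambda_cv, cva)$lambda_star
      }
      fit_b <- tryCatch(fit_cox(Xb, tb, eb, lambda = lam_b, ties = ties,
                                strict = FALSE),
                        error = function(e) NULL)
      if (is.null(fit_b)) { optimism[b] <- NA_real_; next }
      beta_b <- ifelse(is.na(fit_b$beta[, 1]), 0, fit_b$beta[, 1])
      c_boot <- uno_c(tb, eb, as.numeric(Xb %*% beta_b),
                      tau = min(tau, max(tb)), se = FALSE)$c
      c_orig <- uno_c(time, event, as.numeric(X %*% beta_b),
                      tau = tau, se = FALSE)$c
      optimism[b] <- c_boot - c_orig
    }
  })
  if (n_redraws > 0.1 * n_bootstrap)
    warnf("%d bootstrap redraws (> 10%% of %d resamples)", n_redraws,
          n_bootstrap)
  opt_ok <- optimism[!is.na(optimism)]
  if (!length(opt_ok)) stopf("all bootstrap resamples failed")
  mean_opt <- mean(opt_ok)
  corrected <- apparent - mean_opt
  shifted <- apparent - opt_ok
  ci <- if (ci_type == "percentile") {
    unname(quantile(shifted, c(0.025, 0.975), type = 7))
  } else {
    corrected + c(-1, 1) * qnorm(0.975) * stats::sd(shifted)
  }
  sel <- names(beta_full)[beta_full != 0]
  structure(list(selected_features = sel,
                 coefficients = beta_full[beta_full != 0],
                 lambda = lambda_star,
                 apparent_c = apparent, corrected_c = corrected,
                 ci = ci, ci_type = ci_type,
                 better_than_chance = ci[1] > 0.5 || ci[2] < 0.5,
                 optimism = mean_opt, optimism_draws = opt_ok,
                 n_bootstrap = n_bootstrap, n_redraws = n_redraws,
                 n_failed = sum(is.na(optimism)),
                 refit_lambda = refit_lambda, tau = tau, seed = seed),
            class = "multivariable_model")
}

#' @export
print.multivariable_model <- function(x, ...) {
  cat(sprintf(
    "<multivariable_model> lambda=%.4g, apparent C=%.3f, corrected C=%.3f (95%% CI %.3f-%.3f)\n",
    x$lambda, x$apparent_c, x$corrected_c, x$ci[1], x$ci[2]))
  if (length(x$selected_features))
    cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  else cat("  null model (no features selected)\n")
  invisible(x)
}
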
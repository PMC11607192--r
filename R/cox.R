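#' LASSO-penalized Cox proportional-hazards fit
#'
#' Maximizes the tie-corrected Cox partial log-likelihood minus an L1
#' penalty, `-(1/W) l(beta) + lambda * sum(|beta|)` with `W` the total case
#' weight, by iteratively reweighted least squares with coordinate-descent
#' soft thresholding (Efron tie handling by default; Breslow available).
#' Predictors are standardized internally (mean 0, population SD 1) and the
#' coefficients are returned on the original scale. `lambda` may be a
#' decreasing vector, in which case the whole warm-started path is fitted.
#'
#' Rows with missing values are dropped (complete-case) and counted;
#' zero-variance predictors are dropped with a warning and carry `NA`
#' coefficients in the output.
#'
#' @param X Numeric feature matrix (or data frame) with named columns.
#' @param time Observed times.
#' @param event Event indicators (0/1); at least one event required.
#' @param lambda Penalty value(s) >= 0 on the standardized scale.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights Optional nonnegative case weights.
#' @param tol,maxit Convergence tolerance and outer-iteration cap.
#' @param strict If `TRUE` (default) non-convergence at any lambda is an
#'   error with diagnostics. Set `FALSE` in path/resampling contexts, where
#'   the unpenalized end of the path can legitimately diverge (monotone
#'   likelihood with more predictors than events); unconverged entries are
#'   then flagged in `converged` and carry the last stable iterate.
#' @return A `cox_lasso_fit`: list with `beta` (p x n_lambda, original
#'   scale), `beta_std`, `lambda`, `lambda_max`, `loglik`, `n`,
#'   `n_dropped_rows`, `dropped_features`, `ties`, `center`, `scale`.
#' @export
fit_cox <- function(X, time, event, lambda = 0, ties = c("efron", "breslow"),
                    weights = NULL, tol = 1e-8, maxit = 100, strict = TRUE) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (any(lambda < 0)) stopf("lambda must be >= 0")
  weights <- weights %||% rep(1, nrow(X))
  ok <- complete.cases(X) & is.finite(time) & !is.na(event)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]; time <- time[ok]; event <- event[ok]
  weights <- weights[ok]
  if (!nrow(X)) stopf("no complete-case rows")
  if (sum(event) < 1) stopf("no events in the data")

  ctr <- colSums(X * weights) / sum(weights)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(weights * Xc^2) / sum(weights))
  dropped <- colnames(X)[!is.finite(scl) | scl == 0]
  if (length(dropped))
    warnf("dropping zero-variance predictor(s): %s",
          paste(dropped, collapse = ", "))
  keep <- setdiff(colnames(X), dropped)
  if (!length(keep)) stopf("no usable predictors")
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scl[keep], `/`)

  ord <- order(time)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  fit <- cpp_cox_path(Xs[ord, , drop = FALSE], as.numeric(time[ord]),
                      as.integer(event[ord]), as.numeric(weights[ord]),
                      lambda, ties == "efron", tol, maxit, 100L)
  if (strict && !all(fit$converged))
    stopf("Cox coordinate descent failed to converge at lambda = %s (n=%d, events=%d)",
          paste(signif(lambda[!fit$converged], 4), collapse = ", "),
          nrow(Xs), sum(event))
  beta_std <- fit$beta
  rownames(beta_std) <- keep
  beta <- matrix(NA_real_, ncol(X), length(lambda),
                 dimnames = list(colnames(X), signif(lambda, 6)))
  beta[keep, ] <- beta_std / scl[keep]

  structure(list(beta = beta, beta_std = beta_std, lambda = lambda,
                 lambda_max = cox_lambda_max(Xs, time, event, weights,
                                             ties == "efron"),
                 loglik = fit$loglik, converged = fit$converged,
                 n = nrow(X), n_events = sum(event),
                 n_dropped_rows = n_dropped, dropped_features = dropped,
                 ties = ties, center = ctr, scale = scl),
            class = "cox_lasso_fit")
}

#' @export
print.cox_lasso_fit <- function(x, ...) {
  cat(sprintf("<cox_lasso_fit> n=%d (%d events), %d lambda value(s), ties=%s\n",
              x$n, x$n_events, length(x$lambda), x$ties))
  invisible(x)
}

#' Coefficients of a penalized Cox fit
#' @param object A `cox_lasso_fit`.
#' @param lambda Which lambda (defaults to the last = smallest fitted).
#' @param ... Unused.
#' @return Named numeric vector of coefficients on the original scale.
#' @export
coef.cox_lasso_fit <- function(object, lambda = NULL, ...) {
  j <- if (is.null(lambda)) ncol(object$beta) else
    which.min(abs(object$lambda - lambda))
  setNames(object$beta[, j], rownames(object$beta))
}

# Smallest lambda at which every coefficient is zero (standardized X).
cox_lambda_max <- function(Xs, time, event, weights, efron) {
  ord <- order(time)
  d <- cpp_cox_deriv(as.numeric(time[ord]), as.integer(event[ord]),
                     as.numeric(weights[ord]), rep(0, nrow(Xs)), efron)
  g <- crossprod(Xs[ord, , drop = FALSE], d$grad) / sum(weights)
  max(abs(g))
}

#' Log-spaced lambda grid for the LASSO path
#'
#' 100 log-spaced values (by default) from `lambda_max` (the smallest
#' penalty with an all-zero solution) down to `min_ratio * lambda_max`.
#'
#' @param X,time,event,weights As in [fit_cox()].
#' @param n_lambda Grid size.
#' @param min_ratio Ratio of smallest to largest lambda.
#' @param ties Tie handling.
#' @return Decreasing numeric vector.
#' @export
cox_lambda_grid <- function(X, time, event, weights = NULL, n_lambda = 100,
                            min_ratio = 1e-3, ties = "efron") {
  X <- as.matrix(X)
  weights <- weights %||% rep(1, nrow(X))
  ok <- complete.cases(X) & is.finite(time) & !is.na(event)
  X <- X[ok, , drop = FALSE]; time <- time[ok]; event <- event[ok]
  weights <- weights[ok]
  ctr <- colSums(X * weights) / sum(weights)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(weights * Xc^2) / sum(weights))
  keep <- is.finite(scl) & scl > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scl[keep], `/`)
  lmax <- cox_lambda_max(Xs, time, event, weights, ties == "efron")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}
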
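#' Cross-validated LASSO penalty selection by concordance
#'
#' Repeats event-stratified k-fold cross-validation: in each iteration the
#' cohort is split into `n_folds` folds preserving the event fraction, the
#' penalized Cox model is fitted on the training folds over the whole lambda
#' grid, and each held-out fold is scored by Uno's C of the linear predictor.
#' The selected penalty is the lambda with the highest C averaged over all
#' folds and iterations; ties break toward the larger lambda (sparser
#' model). A split producing a fold without events is redrawn (and counted).
#'
#' @param X Feature matrix.
#' @param time,event Survival outcome.
#' @param lambda Decreasing lambda grid; default [cox_lambda_grid()].
#' @param n_iterations Number of repeated CV iterations (the reference
#'   analysis uses 1000).
#' @param n_folds Number of folds (default 3).
#' @param tau Truncation time for Uno's C (per endpoint).
#' @param seed Integer seed; the whole search is deterministic given it.
#' @param ties Tie handling for the Cox fits.
#' @param fit_tol Convergence tolerance of the inner Cox fits; looser than
#'   the final-fit default since only the held-out ranking matters.
#' @return List: `lambda_star`, `cv_c` (mean C per lambda), `cv_c_sd`,
#'   `lambda`, `n_redraws`, `n_iterations`, `n_folds`.
#' @export
select_lambda_cv <- function(X, time, event, lambda = NULL,
                             n_iterations = 1000, n_folds = 3,
                             tau = max(time), seed = 1L, ties = "efron",
                             fit_tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(time) == n, length(event) == n)
  lambda <- lambda %||% cox_lambda_grid(X, time, event, ties = ties)
  lambda <- sort(lambda, decreasing = TRUE)
  if (!length(lambda)) stopf("empty lambda grid")
  if (sum(event) < n_folds)
    stopf("need at least %d events for %d-fold event-stratified CV",
          n_folds, n_folds)
  c_sum <- numeric(length(lambda))
  c_sumsq <- numeric(length(lambda))
  n_scored <- 0L
  n_redraws <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      folds <- NULL
      for (attempt in 1:100) {
        f <- stratified_folds(event, n_folds)
        if (min(tabulate(f[event == 1], n_folds)) >= 1 &&
            min(tabulate(f[event == 0], n_folds)) >= 0) {
          ok_train <- vapply(seq_len(n_folds), function(k)
            sum(event[f != k]) >= 1, logical(1))
          if (all(ok_train)) { folds <- f; break }
        }
        n_redraws <- n_redraws + 1L
      }
      if (is.null(folds)) stopf("could not draw folds with events in each fold")
      for (k in seq_len(n_folds)) {
        tr <- folds != k
        fit <- fit_cox(X[tr, , drop = FALSE], time[tr], event[tr],
                       lambda = lambda, ties = ties, strict = FALSE,
                       tol = fit_tol)
        eta <- X[!tr, , drop = FALSE] %*%
          ifelse(is.na(fit$beta), 0, fit$beta)
        tau_k <- min(tau, max(time[!tr]))
        cs <- uno_c_multi(time[!tr], event[!tr], eta, tau_k)
        cs[is.na(cs)] <- 0.5
        c_sum <- c_sum + cs
        c_sumsq <- c_sumsq + cs^2
        n_scored <- n_scored + 1L
      }
    }
  })
  cv_c <- c_sum / n_scored
  cv_sd <- sqrt(pmax(c_sumsq / n_scored - cv_c^2, 0))
  best <- which(cv_c == max(cv_c))[1]  # grid is decreasing: first = largest
  list(lambda_star = lambda[best], cv_c = cv_c, cv_c_sd = cv_sd,
       lambda = lambda, n_redraws = n_redraws,
       n_iterations = n_iterations, n_folds = n_folds, tau = tau)
}

# Event-stratified fold labels in 1..k.
stratified_folds <- function(event, k) {
  f <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}
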
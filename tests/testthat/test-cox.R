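test_that("unpenalized fit matches coxph (Efron) to 1e-6", {
  d <- sim_ph_data(300, c(0.5, -0.7, 0.2), cens_max = 25, seed = 2)
  f <- fit_cox(d$X, d$time, d$event, lambda = 0)
  cp <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X)
  expect_lt(max(abs(coef(f) - coef(cp))), 1e-6)
})

test_that("a simulated true HR of 2 is recovered within 3 SE at n = 500", {
  set.seed(3)
  x <- rbinom(500, 1, 0.5)
  d <- sim_ph_data(500, log(2), X = cbind(trt = x), cens_max = 40, seed = 3)
  f <- fit_cox(d$X, d$time, d$event, lambda = 0)
  cp <- survival::coxph(survival::Surv(d$time, d$event) ~ x)
  se <- sqrt(vcov(cp)[1, 1])
  expect_lt(abs(coef(f)[["trt"]] - log(2)), 3 * se)
})

test_that("lambda at or above lambda_max zeroes every coefficient", {
  d <- sim_ph_data(150, c(0.8, -0.5), cens_max = 30, seed = 4)
  f0 <- fit_cox(d$X, d$time, d$event, lambda = 0)
  lmax <- f0$lambda_max
  f <- fit_cox(d$X, d$time, d$event, lambda = c(lmax * 1.5, lmax))
  expect_true(all(f$beta == 0))
  f2 <- fit_cox(d$X, d$time, d$event, lambda = lmax * 0.9)
  expect_true(any(f2$beta != 0))
})

test_that("duplicating rows equals case weights 2 under Breslow ties", {
  d <- sim_ph_data(80, c(0.6, -0.4), cens_max = 30, seed = 5)
  idx <- rep(seq_len(80), each = 2)
  f_dup <- fit_cox(d$X[idx, ], d$time[idx], d$event[idx], lambda = 0,
                   ties = "breslow")
  f_w <- fit_cox(d$X, d$time, d$event, lambda = 0, ties = "breslow",
                 weights = rep(2, 80))
  expect_lt(max(abs(coef(f_dup) - coef(f_w))), 1e-7)
})

test_that("penalized solution agrees with glmnet on tie-free data", {
  skip_if_not_installed("glmnet")
  d <- sim_ph_data(250, c(0.7, 0, -0.5, 0), cens_max = 28, seed = 6)
  n <- nrow(d$X)
  Xs <- scale(d$X) * sqrt(n / (n - 1))  # population-SD standardization
  for (lam in c(0.15, 0.05)) {
    g <- glmnet::glmnet(Xs, survival::Surv(d$time, d$event), family = "cox",
                        lambda = lam, standardize = FALSE, thresh = 1e-14)
    mine <- fit_cox(d$X, d$time, d$event, lambda = lam, ties = "breslow")
    expect_lt(max(abs(as.numeric(g$beta) - mine$beta_std[, 1])), 1e-5)
  }
})

test_that("the L1 norm of the path is nonincreasing in lambda", {
  d <- sim_ph_data(120, c(0.9, -0.6, 0.3, 0, 0), cens_max = 30, seed = 7)
  grid <- cox_lambda_grid(d$X, d$time, d$event, n_lambda = 30)
  f <- fit_cox(d$X, d$time, d$event, lambda = grid)
  l1 <- colSums(abs(f$beta_std))
  expect_true(all(diff(l1) >= -1e-8))  # lambda decreasing along the path
  expect_equal(unname(l1[1]), 0, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or dropped as specified", {
  d <- sim_ph_data(60, 0.5, cens_max = 25, seed = 8)
  X <- cbind(d$X, flat = 1)
  expect_warning(f <- fit_cox(X, d$time, d$event, lambda = 0),
                 "zero-variance")
  expect_true(is.na(coef(f)[["flat"]]))
  expect_error(fit_cox(d$X, d$time, rep(0, 60), lambda = 0), "no events")
})
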
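test_that("ols_fit reproduces the normal-equations solution and hat values", {
  set.seed(31)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  fit <- ols_fit(X, y)
  b_oracle <- drop(solve(crossprod(X)) %*% crossprod(X, y))
  expect_rel_equal(coef(fit), b_oracle, 1e-10)
  expect_equal(sum(fit$hat), 5, tolerance = 1e-10)      # tr(H) = p
  expect_true(all(fit$hat >= 0 & fit$hat <= 1))
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-8)

  # orthonormal columns: beta = X'y exactly
  Q <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  fq <- ols_fit(Q, y[1:20])
  expect_equal(coef(fq), drop(crossprod(Q, y[1:20])),
               ignore_attr = TRUE, tolerance = 1e-12)

  # y in the column space: zero residuals
  y0 <- drop(X %*% rnorm(5))
  expect_lt(max(abs(residuals(ols_fit(X, y0)))), 1e-10)

  # rank deficiency is an explicit error, not a silent pseudo-inverse
  expect_error(ols_fit(cbind(X, X[, 1]), y), "rank deficient")
  expect_error(ols_fit(matrix(rnorm(12), 3, 4), rnorm(3)), "p < n")
})

test_that("LOO shortcut equals per-case refits, coefficients included", {
  set.seed(32)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  fit <- ols_fit(X, y)
  cv <- loo(fit, coefficients = TRUE)
  for (i in c(1, 13, 40)) {
    ref <- lm.fit(X[-i, ], y[-i])
    expect_rel_equal(cv$predictions[i], sum(X[i, ] * ref$coefficients), 1e-9)
    expect_rel_equal(cv$coef_loo[i, ], ref$coefficients, 1e-9)
  }
  # LOO residual identity e_loo * (1 - h) = e
  expect_equal((cv$observed - cv$predictions) * (1 - fit$hat),
               residuals(fit), tolerance = 1e-12)
  # case with zero residual: beta_(-i) = beta, zero LOO residual
  y0 <- drop(X %*% rnorm(6))
  cv0 <- loo(ols_fit(X, y0), coefficients = TRUE)
  expect_lt(max(abs(cv0$errors)), 1e-8)
})

test_that("leave-d-out shortcut equals refits; d = 1 reduces to LOO", {
  set.seed(33)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  fit <- ols_fit(X, y)
  idx <- c(4, 9, 23, 31, 50)
  cvd <- leave_d_out(fit, idx)
  expect_rel_equal(cvd$predictions, oracle_ols_refit(X, y, idx), 1e-9)
  expect_equal(cvd$pmse, mean(cvd$errors^2), tolerance = 1e-12)

  cv1 <- leave_d_out(fit, 17L)
  cvl <- loo(fit)
  expect_equal(cv1$predictions, cvl$predictions[17], tolerance = 1e-12)

  # average of singleton leave-d-out PMSEs equals LOO PMSE exactly
  singles <- leave_d_out(fit, as.list(1:50))
  expect_equal(singles$pmse, cvl$pmse, tolerance = 1e-12)

  expect_error(leave_d_out(fit, integer(0)), "empty")
})

test_that("singular (I - H_d) falls back to a generalized inverse with
          predictions invariant and flagged", {
  set.seed(34)
  n <- 20; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit <- ols_fit(X, y)
  idx <- 1:15                                 # d > n - p: singular block
  cvd <- leave_d_out(fit, idx)
  expect_true(cvd$rank_deficient)
  expect_true(all(is.finite(cvd$predictions)))
})

test_that("expected LOO PMSE matches per-case decomposition and d = 1", {
  set.seed(35)
  X <- matrix(rnorm(30 * 4), 30, 4)
  h <- rowSums(qr.Q(qr(X))^2)
  s2 <- 1.3
  # LOO formula equals the average of singleton leave-d-out evaluations
  loo_val <- expected_pmse_ols(X, sigma2_e = s2)
  singles <- vapply(1:30, function(i)
    expected_pmse_ols(X, i, sigma2_e = s2), numeric(1))
  expect_equal(loo_val, mean(singles), tolerance = 1e-10)
  # orthogonal test row: expected PMSE = sigma2_e exactly
  Xo <- rbind(matrix(rnorm(20 * 3), 20, 3), 0)
  Xo[21, ] <- 0
  # H_d = 0 when the test row is the zero vector
  expect_equal(expected_pmse_ols(Xo[1:21, ], 21, sigma2_e = s2), s2,
               tolerance = 1e-10)
})
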
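# Brute-force refit oracles: every shortcut identity in the package is
# checked against these independent implementations, which always refit on
# the training rows using plain normal-equation / kernel-block solves.

oracle_ols_refit <- function(X, y, test) {
  b <- solve(crossprod(X[-test, , drop = FALSE]),
             crossprod(X[-test, , drop = FALSE], y[-test]))
  drop(X[test, , drop = FALSE] %*% b)
}

oracle_ridge_refit <- function(X, y, lambda, test) {
  Xt <- X[-test, , drop = FALSE]
  b <- solve(crossprod(Xt) + diag(lambda, ncol(X)), crossprod(Xt, y[-test]))
  drop(X[test, , drop = FALSE] %*% b)
}

oracle_kernel_refit <- function(K, y, lambda, test) {
  ntr <- length(y) - length(test)
  drop(K[test, -test, drop = FALSE] %*%
         solve(K[-test, -test, drop = FALSE] + diag(lambda, ntr), y[-test]))
}

# two-kernel BLUP refit via the joint-covariance form: with lambda = s2e/s2,
# E(g_P,test | y_tr) = K_P[test,tr] (K_P + (lP/lM) K_M + lP I)[tr,tr]^{-1} y_tr
oracle_bikernel_refit <- function(K_P, K_M, y, lambda_P, lambda_M, test) {
  tr <- setdiff(seq_along(y), test)
  n_tr <- length(tr)
  VP <- K_P[tr, tr] + (lambda_P / lambda_M) * K_M[tr, tr] +
    diag(lambda_P, n_tr)
  VM <- K_M[tr, tr] + (lambda_M / lambda_P) * K_P[tr, tr] +
    diag(lambda_M, n_tr)
  predP <- drop(K_P[test, tr, drop = FALSE] %*% solve(VP, y[tr]))
  predM <- drop(K_M[test, tr, drop = FALSE] %*% solve(VM, y[tr]))
  predP + predM
}

# random PSD kernel with controllable rank deficiency
random_psd <- function(n, rank = n) {
  A <- matrix(stats::rnorm(n * rank), n, rank)
  tcrossprod(A) / rank
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  scale <- max(abs(expected), 1e-8)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
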
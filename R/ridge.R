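#' Ridge regression / BLUP of marker effects at fixed shrinkage
#'
#' Fits `beta_r = (X'X + I lambda)^{-1} X'y` with `lambda = sigma2_e /
#' sigma2_b` treated as known.  Computation goes through the dual identity
#' `beta_r = X'(XX' + I lambda)^{-1} y`, so `p >> n` costs only an n x n
#' eigendecomposition, which is cached and reused by the cross-validation
#' methods (the ridge smoother `X C^{-1} X'` equals `G(G + I lambda)^{-1}`
#' with `G = XX'`).  `lambda = 0` (the OLS limit) is permitted only for
#' full-rank `X` with `p < n` and is computed by QR.
#'
#' @param X n x p marker matrix, centered (no intercept; center `y` too).
#' @param y numeric phenotype vector.
#' @param lambda shrinkage factor `>= 0`.
#' @return Object of class `"ridge_fit"`: `coefficients`, `residuals`,
#'   `fitted.values`, `hat` (diagonal `h_ii^r` of the ridge smoother),
#'   `lambda`, plus cached eigendecomposition of `XX'`.
#' @examples
#' X <- center(matrix(rbinom(200, 1, 0.5), 10, 20))
#' y <- center(rnorm(10))
#' fit <- ridge_fit(X, y, lambda = 5)
#' loo(fit)$pmse
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(lambda) == 1L, lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  if (lambda == 0 && p >= n)
    stop("lambda = 0 requires full-rank X with p < n")
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  d[d < 1e-12 * max(d)] <- 0      # numerical rank: exact zeros, not noise
  if (lambda == 0) {
    qrX <- qr(X)
    if (qrX$rank < p) stop("lambda = 0 requires full column rank X")
    beta <- qr.coef(qrX, y)
    Q <- qr.Q(qrX)
    h <- rowSums(Q^2)
  } else {
    if (p <= n) {
      # primal route: numerically safer when XX' is rank deficient and
      # lambda is tiny (zero eigendirections would amplify rounding noise)
      beta <- drop(solve(crossprod(X) + diag(lambda, p), crossprod(X, y)))
    } else {
      # dual route: (G + I lambda)^{-1} y through the eigenbasis
      uy <- drop(crossprod(eg$vectors, y))
      beta <- drop(crossprod(X, eg$vectors %*% (uy / (d + lambda))))
    }
    # h_ii^r = diag of G (G + I lambda)^{-1} = sum_k U_ik^2 d_k/(d_k+lambda)
    h <- rowSums(sweep(eg$vectors^2, 2L, d / (d + lambda), "*"))
  }
  fitted <- drop(X %*% beta)
  structure(list(coefficients = beta, residuals = y - fitted,
                 fitted.values = fitted, hat = h, lambda = lambda,
                 eigen_G = list(vectors = eg$vectors, values = d),
                 X = X, y = y, n = n, p = p),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge/SNP-BLUP fit: n = %d, p = %d, lambda = %g\n",
              x$n, x$p, x$lambda))
  cat(sprintf("  p_eff = %.2f, residual SS = %.6g\n",
              sum(x$hat), sum(x$residuals^2)))
  invisible(x)
}

#' @export
coef.ridge_fit <- function(object, ...) object$coefficients

#' @export
residuals.ridge_fit <- function(object, ...) object$residuals

#' @export
fitted.ridge_fit <- function(object, ...) object$fitted.values

#' @export
predict.ridge_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  drop(as.matrix(newdata) %*% object$coefficients)
}

# Test-block of the ridge/kernel smoother from the cached eigen pair.
smoother_block <- function(eigen_G, lambda, idx) {
  U <- eigen_G$vectors[idx, , drop = FALSE]
  f <- eigen_G$values / (eigen_G$values + lambda)
  U %*% (t(U) * f)
}

#' @describeIn ridge_fit Exact leave-one-out CV at fixed `lambda`: held-out
#'   residual `e_i^r / (1 - h_ii^r)`; downdated coefficients
#'   `beta_r - C^{-1} x_i e_i^r / (1 - h_ii^r)` available via
#'   `coefficients = TRUE` (computed K^{-1}-free through
#'   `C^{-1}X' = X'(XX' + I lambda)^{-1}`).
#' @param object a `ridge_fit`.
#' @param coefficients if TRUE, include the n x p matrix `coef_loo`.
#' @param ... unused.
#' @export
loo.ridge_fit <- function(object, coefficients = FALSE, ...) {
  h <- object$hat
  if (any(h >= 1 - 1e-12))
    stop("smoother diagonal ~ 1 at case(s) ",
         paste(which(h >= 1 - 1e-12), collapse = ", "))
  e_loo <- object$residuals / (1 - h)
  pred <- object$y - e_loo
  extra <- list()
  if (coefficients) {
    eg <- object$eigen_G
    lam <- object$lambda
    if (lam == 0) {
      A <- xtx_solve(qr(object$X), t(object$X))
    } else if (object$p <= object$n) {
      A <- solve(crossprod(object$X) + diag(lam, object$p), t(object$X))
    } else {
      W <- t(eg$vectors) / (eg$values + lam)     # diag(1/(d+l)) U'
      A <- crossprod(object$X, eg$vectors) %*% W # p x n = C^{-1} X'
    }
    step <- sweep(A, 2L, object$residuals / (1 - h), "*")
    extra$coef_loo <- t(object$coefficients - step)
  }
  new_cv_result(pred, object$y, "ridge LOO", extra = extra)
}

#' @describeIn ridge_fit Exact leave-d-out CV at fixed `lambda`: with
#'   `H_d^r = X_d C^{-1} X_d'` (a block of the ridge smoother), prediction
#'   errors are `(I - H_d^r)^{-1} e_d^r`.  For `lambda > 0` the block's
#'   eigenvalues are `< 1`, so the system is always nonsingular.
#' @param test_sets index vector or list of index vectors; duplicated
#'   indices (with-replacement layouts) are deduplicated for training
#'   removal, each sampled instance scored.
#' @export
leave_d_out.ridge_fit <- function(object, test_sets, ...) {
  y <- object$y
  lam <- object$lambda
  Q0 <- if (lam == 0) qr.Q(qr(object$X)) else NULL
  engine <- function(idx) {
    u <- unique(idx)
    Hd <- if (lam == 0) tcrossprod(Q0[u, , drop = FALSE])
          else smoother_block(object$eigen_G, lam, u)
    pe <- solve(diag(length(u)) - Hd, object$residuals[u])
    pred_u <- y[u] - pe
    list(pred = pred_u[match(idx, u)], flag = FALSE)
  }
  run_layout(test_sets, engine, function(idx) y[idx], "ridge leave-d-out")
}

#' Expected prediction mean squared error for ridge LOO
#'
#' Closed form of the expected realized LOO PMSE under the generating model
#' `y = X beta + e`, `beta ~ N(0, I sigma2_e/lambda)`, `e ~ N(0, I sigma2_e)`:
#' `(1/n) delta' D_r delta + (sigma2_e/n) tr[D_r M_r (XX' lambda^{-1} + I) M_r]`
#' with `D_r = diag((1-h_ii^r)^{-2})` and `M_r = I - X C^{-1} X'`.
#'
#' @param X centered n x p marker matrix.
#' @param lambda shrinkage factor `> 0`.
#' @param delta length-n bias vector (0 for the unbiased model).
#' @param sigma2_e residual variance `> 0`.
#' @return expected LOO PMSE (scalar).
#' @export
expected_pmse_ridge <- function(X, lambda, delta = NULL, sigma2_e = 1) {
  stopifnot(lambda > 0, sigma2_e > 0)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(delta)) delta <- numeric(n)
  stopifnot(length(delta) == n)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  d[d < 1e-12 * max(d)] <- 0      # numerical rank: exact zeros, not noise
  H <- eg$vectors %*% (t(eg$vectors) * (d / (d + lambda)))
  h <- diag(H)
  Dr <- 1 / (1 - h)^2
  M <- diag(n) - H
  V <- M %*% (G / lambda + diag(n)) %*% M     # Var(y - X beta_r) / sigma2_e
  mean(Dr * delta^2) + sigma2_e * sum(Dr * diag(V)) / n
}
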
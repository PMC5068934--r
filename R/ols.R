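#' Ordinary least-squares fit with cached cross-validation quantities
#'
#' Fits `y = X beta + e` by OLS and caches the residuals, leverages
#' `h_ii = x_i'(X'X)^{-1}x_i` and the QR factorization of `X`, from which
#' every leave-one-out and leave-d-out prediction follows in closed form
#' ([loo()], [leave_d_out()]).
#'
#' @param X n x p numeric marker/design matrix with `rank(X) = p < n`.
#' @param y numeric phenotype vector of length n.
#' @param intercept if TRUE, a constant column is appended to `X` (its
#'   leverage contribution is then included in `h_ii`).
#' @return An object of class `"ols_fit"` with components `coefficients`,
#'   `residuals`, `fitted.values`, `hat`, `qr`, `X`, `y`, `intercept`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- rnorm(20)
#' fit <- ols_fit(X, y)
#' loo(fit)$pmse
#' @export
ols_fit <- function(X, y, intercept = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (p >= n) stop("OLS requires p < n (got p = ", p, ", n = ", n, ")")
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("X is rank deficient: rank ", qrX$rank, " < p = ", p,
         "; remove collinear columns or use ridge_fit()")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  structure(list(coefficients = beta, residuals = y - fitted,
                 fitted.values = fitted, hat = h, qr = qrX,
                 X = X, y = y, intercept = intercept, n = n, p = p),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, p = %d%s\n", x$n, x$p,
              if (x$intercept) " (incl. intercept)" else ""))
  cat(sprintf("  residual SS = %.6g, max leverage = %.4f\n",
              sum(x$residuals^2), max(x$hat)))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted.values

#' @export
predict.ols_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (object$intercept) newdata <- cbind(1, newdata)
  drop(newdata %*% object$coefficients)
}

# (X'X)^{-1} v through the cached QR: solves R'R z = v.
xtx_solve <- function(qrX, v) {
  R <- qr.R(qrX)
  backsolve(R, forwardsolve(t(R), v))
}

#' @describeIn ols_fit Exact leave-one-out CV: the held-out residual is
#'   `e_i / (1 - h_ii)` and the downdated coefficients are
#'   `beta - (X'X)^{-1} x_i e_i / (1 - h_ii)`, both from the full fit alone.
#' @param object an `ols_fit` object.
#' @param coefficients if TRUE, return the n x p matrix of leave-one-out
#'   coefficient vectors in component `coef_loo`.
#' @param ... unused.
#' @export
loo.ols_fit <- function(object, coefficients = FALSE, ...) {
  h <- object$hat
  if (any(h >= 1 - 1e-12))
    stop("self-determined case(s) with leverage ~ 1: ",
         paste(which(h >= 1 - 1e-12), collapse = ", "))
  e_loo <- object$residuals / (1 - h)         # observed - predicted
  pred <- object$y - e_loo
  extra <- list()
  if (coefficients) {
    # beta_(-i) = beta - (X'X)^{-1} x_i e_i/(1-h_ii), all i at once
    A <- xtx_solve(object$qr, t(object$X))    # p x n, columns (X'X)^{-1}x_i
    step <- sweep(A, 2L, object$residuals / (1 - h), "*")
    extra$coef_loo <- t(object$coefficients - step)
  }
  new_cv_result(pred, object$y, "OLS LOO", extra = extra)
}

#' @describeIn ols_fit Exact leave-d-out CV: with `H_d = X_d (X'X)^{-1} X_d'`,
#'   held-out prediction errors are `(I - H_d)^{-1} e_d`.  A singular
#'   `(I - H_d)` (possible when `d > n - p`) is handled by Moore-Penrose
#'   generalized inverse and flagged via `rank_deficient`.
#' @param test_sets indices (or list of index sets) to hold out; repeated
#'   indices within a set (with-replacement layouts) are deduplicated for
#'   training removal and each sampled instance is scored.
#' @export
leave_d_out.ols_fit <- function(object, test_sets, ...) {
  X <- object$X; y <- object$y
  engine <- function(idx) {
    u <- unique(idx)
    Xd <- X[u, , drop = FALSE]
    Hd <- Xd %*% xtx_solve(object$qr, t(Xd))
    M <- diag(length(u)) - Hd
    ed <- object$residuals[u]
    flag <- FALSE
    pe <- tryCatch(solve(M, ed), error = function(e) {
      flag <<- TRUE
      drop(MASS::ginv(M) %*% ed)
    })
    pred_u <- y[u] - pe
    list(pred = pred_u[match(idx, u)], flag = flag)
  }
  run_layout(test_sets, engine, function(idx) y[idx], "OLS leave-d-out")
}

#' Expected prediction mean squared error for OLS cross-validation
#'
#' Closed-form expectation of the realized PMSE over the distribution of
#' `y = X beta + e`, `e ~ N(0, I sigma2_e)`:
#' `E[PMSE(d)] = (1/d) { delta'(I-H_d)^{-2} delta + tr[(I-H_d)^{-1}] sigma2_e }`,
#' with `H_d` the test block of the hat matrix and `delta` the prediction
#' bias (zero for a correctly specified model).  With `test_indices = NULL`
#' the leave-one-out version is returned, averaging the per-case terms
#' `delta_i^2/(1-h_ii)^2 + sigma2_e/(1-h_ii)` over all n cases.
#'
#' @param X n x p design matrix (include the intercept column yourself or via
#'   `cbind(1, X)` to match the fit).
#' @param test_indices held-out row indices, or NULL for the LOO average.
#' @param delta bias vector (length d, or length n for LOO); defaults to 0.
#' @param sigma2_e residual variance, `> 0`.
#' @return expected PMSE (scalar).
#' @export
expected_pmse_ols <- function(X, test_indices = NULL, delta = NULL,
                              sigma2_e = 1) {
  stopifnot(sigma2_e > 0)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("X is rank deficient")
  if (is.null(test_indices)) {
    h <- rowSums(qr.Q(qrX)^2)
    if (is.null(delta)) delta <- numeric(nrow(X))
    # Var(y_i - x_i' beta_hat) = (1 - h_ii) sigma2_e on the diagonal
    return(mean(delta^2 / (1 - h)^2 + sigma2_e / (1 - h)))
  }
  idx <- unique(as.integer(test_indices))
  d <- length(idx)
  if (is.null(delta)) delta <- numeric(d)
  stopifnot(length(delta) == d)
  Xd <- X[idx, , drop = FALSE]
  M <- diag(d) - Xd %*% xtx_solve(qrX, t(Xd))
  Minv <- tryCatch(solve(M), error = function(e) MASS::ginv(M))
  (drop(crossprod(Minv %*% delta)) + sum(diag(Minv)) * sigma2_e) / d
}
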
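#' Effective number of parameters of a shrinkage fit
#'
#' Model complexity under ridge/BLUP shrinkage is the trace of the smoother
#' matrix: `p_eff = tr[X (X'X + I lambda)^{-1} X']` for marker regression, or
#' equivalently `tr[K (K + I lambda)^{-1}]` for a kernel `K` (with `K = XX'`
#' the two coincide).  The effective residual degrees of freedom are
#' `nu_e = n - p_eff`.  Both are computed from the eigenvalues of the n x n
#' Gram/kernel matrix, so singular `K` never requires `K^{-1}`, and a whole
#' `lambda` grid reuses one decomposition.
#'
#' @param object an n x p marker matrix, or an n x n symmetric kernel matrix,
#'   or a numeric vector of precomputed Gram/kernel eigenvalues.
#' @param lambda shrinkage factor(s) `sigma2_e / sigma2_b`, `>= 0`; `lambda = 0`
#'   gives the OLS limit `p_eff = rank`.
#' @param n training sample size; required only when `object` is an
#'   eigenvalue vector.
#' @return For scalar `lambda`, a list of class `"complexity_report"` with
#'   `p_eff`, `nu_e`, `n_train`, `lambda`; for vector `lambda` a data.frame
#'   with one row per `lambda` value.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' effective_parameters(X, lambda = c(0, 1, 10))
#' @export
effective_parameters <- function(object, lambda, n = NULL) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (is.matrix(object)) {
    n <- nrow(object)
    d <- gram_eigenvalues(object)
  } else {
    if (is.null(n)) stop("supply n when passing precomputed eigenvalues")
    d <- pmax(as.numeric(object), 0)
  }
  one <- function(l) {
    if (l == 0) sum(d > 1e-10 * max(d, 1)) else sum(d / (d + l))
  }
  p_eff <- vapply(lambda, one, numeric(1))
  if (length(lambda) > 1L)
    return(data.frame(lambda = lambda, p_eff = p_eff, nu_e = n - p_eff))
  structure(list(p_eff = p_eff, nu_e = n - p_eff, n_train = n,
                 lambda = lambda),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf(
    "Effective parameters: p_eff = %.4f, nu_e = %.4f (n = %d, lambda = %g)\n",
    x$p_eff, x$nu_e, x$n_train, x$lambda))
  invisible(x)
}

#' Effective residual degrees of freedom of a training subset
#'
#' `nu_e = (n - d) - tr[X_train (X_train' X_train + I lambda)^{-1} X_train']`
#' where `X_train` is the marker matrix after removing the test rows.  The
#' trace is evaluated through whichever Gram matrix (p x p or (n-d) x (n-d))
#' is smaller.
#'
#' @param X full n x p marker matrix.
#' @param lambda shrinkage factor(s) `> 0` (0 allowed for full-rank training X).
#' @param test_indices row indices of the held-out cases (possibly empty).
#' @return `nu_e` value(s), one per `lambda`.
#' @export
effective_residual_df <- function(X, lambda, test_indices = integer(0)) {
  test_indices <- unique(as.integer(test_indices))
  Xt <- if (length(test_indices)) X[-test_indices, , drop = FALSE] else X
  rep <- effective_parameters(Xt, lambda)
  if (is.data.frame(rep)) rep$nu_e else rep$nu_e
}

# Eigenvalues of XX' (markers) or of K itself (square symmetric input),
# clipped to >= 0.  The smaller of the two Gram forms is decomposed.
gram_eigenvalues <- function(object) {
  if (nrow(object) == ncol(object) &&
      max(abs(object - t(object))) <= 1e-8 * max(1, max(abs(object)))) {
    d <- eigen(object, symmetric = TRUE, only.values = TRUE)$values
  } else {
    G <- if (nrow(object) <= ncol(object)) tcrossprod(object)
         else crossprod(object)
    d <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  }
  pmax(d, 0)
}
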
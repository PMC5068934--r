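#' Linear (genomic relationship) kernel
#'
#' `G = XX'/c`.  With `c = 1` the shrinkage factor `lambda` used for BLUP of
#' marker effects carries over unchanged to GBLUP; other scale constants
#' (e.g. `c = p`) rescale `lambda` accordingly, which is why the constant is
#' recorded on the result.
#'
#' @param X n x p marker matrix (centered recommended).
#' @param scale `"none"` (c = 1), `"p"` (c = ncol(X)), or a positive number.
#' @return n x n matrix with attributes `provenance = "linear_xx"`,
#'   `scale_constant`, and rownames/colnames from `rownames(X)`.
#' @export
linear_kernel <- function(X, scale = c("none", "p")) {
  X <- as.matrix(X)
  cc <- if (is.numeric(scale)) {
    stopifnot(scale > 0); scale
  } else {
    switch(match.arg(scale), none = 1, p = ncol(X))
  }
  G <- tcrossprod(X) / cc
  rownames(G) <- colnames(G) <- rownames(X)
  attr(G, "provenance") <- "linear_xx"
  attr(G, "scale_constant") <- cc
  G
}

#' Multi-bandwidth Gaussian kernel
#'
#' Builds `k_ij = sum_m w_m exp(-h_m d_ij / max(d_ij))` from squared
#' Euclidean marker distances `d_ij = (x_i - x_j)'(x_i - x_j)` normalized by
#' their maximum over all pairs.  Small bandwidths give "global" similarity
#' (entries near 1), large bandwidths "local" similarity; weights must lie in
#' (0, 1] and sum to 1, making the diagonal exactly 1 and all entries lie in
#' \[0, 1\].  A single-bandwidth kernel is `w = 1`.
#'
#' @param X n x p marker matrix.
#' @param h positive bandwidths (default `c(0.5, 2, 4)`: global, regional,
#'   local).
#' @param w weights, same length as `h`, in (0, 1], summing to 1.
#' @return The combined n x n kernel with attributes `provenance =
#'   "gaussian_multi"`, `h`, `w`, and `components` (list of the
#'   single-bandwidth matrices).
#' @export
gaussian_multikernel <- function(X, h = c(0.5, 2, 4), w = c(0.5, 0.3, 0.2)) {
  X <- as.matrix(X)
  stopifnot(length(h) == length(w), all(h > 0), all(w > 0), all(w <= 1))
  if (abs(sum(w) - 1) > 1e-10) stop("weights must sum to 1 (got ", sum(w), ")")
  D <- as.matrix(stats::dist(X))^2
  dmax <- max(D)
  if (dmax == 0) stop("all rows of X identical: pairwise distances are 0")
  Dn <- D / dmax
  comps <- lapply(h, function(hm) {
    Km <- exp(-hm * Dn)
    rownames(Km) <- colnames(Km) <- rownames(X)
    Km
  })
  K <- Reduce(`+`, Map(`*`, w, comps))
  rownames(K) <- colnames(K) <- rownames(X)
  attr(K, "provenance") <- "gaussian_multi"
  attr(K, "h") <- h
  attr(K, "w") <- w
  attr(K, "components") <- comps
  K
}

#' Validate a kernel/relationship matrix
#'
#' Checks symmetry and positive semidefiniteness (smallest eigenvalue
#' `>= -1e-8 x` largest in magnitude) and reports the condition number and a
#' singularity flag relevant to code paths that would form `K^{-1}` (none in
#' this package do, but user-supplied kernels may be consumed elsewhere).
#'
#' @param K square numeric matrix.
#' @param tol relative eigenvalue tolerance for PSD.
#' @return list with `symmetric`, `psd`, `min_eigenvalue`, `max_eigenvalue`,
#'   `condition`, `singular`.  Errors if asymmetric beyond 1e-8 or not PSD.
#' @export
validate_kernel <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel must be square")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8 * max(1, max(abs(K))))
    stop("kernel asymmetric: max |K - K'| = ", format(asym))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev))
  if (min(ev) < -tol * max(mx, 1))
    stop("kernel not positive semidefinite: min eigenvalue ", format(min(ev)))
  singular <- min(ev) < tol * mx
  list(symmetric = TRUE, psd = TRUE,
       min_eigenvalue = min(ev), max_eigenvalue = max(ev),
       condition = if (singular) Inf else mx / min(ev),
       singular = singular)
}
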
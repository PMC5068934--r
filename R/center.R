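#' Center a marker matrix or phenotype vector
#'
#' Subtracts column means (matrix) or the mean (vector) and stores the removed
#' means so that predictions can be mapped back to the original scale.  All
#' shortcut cross-validation identities in this package assume centered
#' phenotypes and markers (or an explicit intercept column); centering also
#' makes the \{0,1\} and \{-1,0,1\} marker codings equivalent up to a column
#' shift.
#'
#' @param x numeric matrix (individuals x markers) or numeric vector.
#' @return An object of the same shape as `x` with attribute `"centers"`
#'   holding the subtracted means and attribute `"centered" = TRUE`.
#'   Centering an already-centered object is a no-op up to floating point.
#' @examples
#' X <- matrix(c(1, 0, 1, 0), ncol = 1)
#' center(X)
#' @export
center <- function(x) {
  if (is.matrix(x)) {
    if (anyNA(x)) {
      bad <- which(colSums(is.na(x)) > 0)
      nm <- colnames(x)[bad]
      if (is.null(nm)) nm <- as.character(bad)
      stop("missing values in column(s): ", paste(nm, collapse = ", "))
    }
    mu <- colMeans(x)
    out <- sweep(x, 2L, mu, "-")
  } else {
    if (anyNA(x)) stop("missing values in input vector")
    mu <- mean(x)
    out <- x - mu
  }
  attr(out, "centers") <- mu
  attr(out, "centered") <- TRUE
  out
}

#' Test whether an object is centered within tolerance
#' @param x numeric matrix or vector.
#' @param tol absolute tolerance on the (column) means.
#' @return logical scalar.
#' @export
is_centered <- function(x, tol = 1e-10) {
  m <- if (is.matrix(x)) colMeans(x) else mean(x)
  all(abs(m) < tol)
}
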
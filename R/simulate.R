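#' Simulate biallelic marker genotypes
#'
#' Independent loci with per-locus allele frequency drawn uniformly in
#' `maf_range`.  Binary coding (presence/absence markers such as DArT) draws
#' Bernoulli(f); additive coding draws Binomial(2, f) - 1, giving codes
#' \{-1, 0, 1\}.  Monomorphic columns are resampled up to a retry cap.
#'
#' @param n individuals, `>= 2`.
#' @param p loci, `>= 1`.
#' @param maf_range numeric length-2, `0 < low <= high <= 0.5`.
#' @param coding `"binary01"` or `"additive_m101"`.
#' @param seed integer seed; the matrix is a pure function of it.
#' @param max_retry resampling attempts per monomorphic column.
#' @return n x p integer-valued matrix with rownames `id_1..id_n`, colnames
#'   `mk_1..mk_p`, and attributes `coding`, `freqs`, `seed`.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5),
                               coding = c("binary01", "additive_m101"),
                               seed = NULL, max_retry = 50L) {
  coding <- match.arg(coding)
  stopifnot(n >= 2, p >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[1] <= maf_range[2],
            maf_range[2] <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(p, maf_range[1], maf_range[2])
  draw <- function(fj) {
    if (coding == "binary01") stats::rbinom(n, 1L, fj)
    else stats::rbinom(n, 2L, fj) - 1L
  }
  X <- vapply(f, draw, numeric(n))
  for (j in seq_len(p)) {
    tries <- 0L
    while (length(unique(X[, j])) == 1L) {
      tries <- tries + 1L
      if (tries > max_retry)
        stop("column ", j, " monomorphic after ", max_retry, " resamples")
      X[, j] <- draw(f[j])
    }
  }
  dimnames(X) <- list(paste0("id_", seq_len(n)), paste0("mk_", seq_len(p)))
  attr(X, "coding") <- coding
  attr(X, "freqs") <- f
  attr(X, "seed") <- seed
  X
}

#' Simulate phenotypes under the additive marker model
#'
#' `y = X beta + e` with `beta ~ N(0, I sigma2_b)` and `e ~ N(0, I sigma2_e)`;
#' the generating truth (effects, genetic values, signal proportion) is
#' returned alongside.
#'
#' @param X marker matrix (centered or not; the truth records `g = X beta`
#'   for the matrix as given).
#' @param sigma2_b marker-effect variance `>= 0`.
#' @param sigma2_e residual variance `>= 0` (not both 0).
#' @param seed integer seed.
#' @return list with `y` (named like `rownames(X)`) and `truth`, a list
#'   holding `beta_true`, `g_true`, `e`, `sigma2_b`, `sigma2_e`,
#'   `signal_ratio` (= var(g)/var(y)), `seed`.
#' @export
simulate_phenotypes <- function(X, sigma2_b, sigma2_e, seed = NULL) {
  stopifnot(sigma2_b >= 0, sigma2_e >= 0, sigma2_b + sigma2_e > 0)
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  beta <- stats::rnorm(ncol(X), 0, sqrt(sigma2_b))
  e <- stats::rnorm(nrow(X), 0, sqrt(sigma2_e))
  g <- drop(X %*% beta)
  y <- g + e
  names(y) <- rownames(X)
  list(y = y,
       truth = list(beta_true = beta, g_true = g, e = e,
                    sigma2_b = sigma2_b, sigma2_e = sigma2_e,
                    signal_ratio = stats::var(g) / stats::var(y),
                    seed = seed))
}

#' Random cross-validation layouts
#'
#' Draws `replicates` testing sets of size `d` from `1:n`, either without
#' replacement within each set (distinct indices) or with replacement, as
#' used for resampled layouts.  With-replacement sets may contain repeated
#' indices; the CV engines deduplicate them for training removal and score
#' every sampled instance.
#'
#' @param n sample size.
#' @param d testing-set size, `1 <= d < n`.
#' @param replicates number of sets.
#' @param replacement draw indices with replacement?
#' @param seed integer seed.
#' @param exhaustive if TRUE with `d = 1`, return the n singleton LOO sets.
#' @return list of integer vectors (class `"cv_layout"`, attributes `d`,
#'   `replacement`, `seed`).
#' @export
make_cv_layouts <- function(n, d, replicates, replacement = FALSE,
                            seed = NULL, exhaustive = FALSE) {
  stopifnot(n >= 2, d >= 1)
  if (d >= n) stop("d must be < n")
  if (exhaustive) {
    if (d != 1L) stop("exhaustive mode requires d = 1")
    sets <- as.list(seq_len(n))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sets <- replicate(replicates,
                      sample.int(n, d, replace = replacement),
                      simplify = FALSE)
  }
  structure(sets, class = c("cv_layout", "list"),
            d = d, replacement = replacement, seed = seed)
}

#' Fixed toy instance for regression tests and examples
#'
#' A deterministic 8 x 3 marker matrix (binary coding) and a length-8
#' phenotype vector; tiny enough that every OLS/ridge/kernel CV quantity can
#' be verified by hand or by brute-force refitting.
#'
#' @return list with `X` (8 x 3, centered copy in `Xc`), `y` (centered in
#'   `yc`).
#' @export
toy_fixture <- function() {
  X <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0,
                0, 1, 1, 0, 0, 1, 1, 0,
                1, 1, 0, 0, 1, 0, 0, 1), nrow = 8,
              dimnames = list(paste0("id_", 1:8), paste0("mk_", 1:3)))
  y <- c(1.20, -0.45, 0.83, -1.31, 0.62, 0.10, -0.74, -0.25)
  names(y) <- rownames(X)
  list(X = X, Xc = center(X), y = y, yc = center(y))
}
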
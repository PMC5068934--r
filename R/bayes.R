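#' Direct posterior sampler for GBLUP with known variance components
#'
#' With `lambda` and `sigma2_e` known, the posterior of the genetic values is
#' `g | y ~ N(g_hat, H sigma2_e)` with `g_hat = G(G + I lambda)^{-1} y` and
#' `H = G(G + I lambda)^{-1}`: no MCMC is needed.  Independent draws are
#' generated through one eigendecomposition of `G` (singular-safe covariance
#' factorization).
#'
#' @param y phenotype vector (centered).
#' @param G n x n symmetric PSD relationship matrix.
#' @param lambda shrinkage factor `> 0`.
#' @param sigma2_e residual variance `> 0`.
#' @param S number of independent draws.
#' @param seed integer seed (draws are reproducible given the seed).
#' @return Object of class `"posterior_samples"`: `g_draws` (S x n),
#'   `sigma2_e_draws`, `sigma2_g_draws` (constants here), `g_hat`, `meta`.
#' @export
direct_gblup_sampler <- function(y, G, lambda, sigma2_e, S, seed = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n, lambda > 0, sigma2_e > 0, S >= 1)
  if (!is.null(seed)) set.seed(seed)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("G is not positive semidefinite")
  f <- d / (d + lambda)
  g_hat <- drop(eg$vectors %*% (f * drop(crossprod(eg$vectors, y))))
  # cov = U diag(f) U' sigma2_e  =>  g = g_hat + U diag(sqrt(f sigma2_e)) z
  sd_t <- sqrt(f * sigma2_e)
  Z <- matrix(stats::rnorm(S * n), n, S) * sd_t
  g_draws <- t(g_hat + eg$vectors %*% Z)
  structure(list(g_draws = g_draws,
                 sigma2_e_draws = rep(sigma2_e, S),
                 sigma2_g_draws = rep(sigma2_e / lambda, S),
                 g_hat = g_hat,
                 meta = list(sampler = "direct", S = S, seed = seed,
                             burn_in = 0L, thin = 1L, lambda = lambda)),
            class = "posterior_samples")
}

#' Gibbs sampler for Bayesian GBLUP
#'
#' Hierarchical model `y = g + e`, `g | sigma2_g ~ N(0, G sigma2_g)`,
#' `e ~ N(0, I sigma2_e)`, with scaled inverse chi-square priors
#' `sigma2_g ~ S_g2 nu_g / chisq(nu_g)` and `sigma2_e ~ S_e2 nu_e /
#' chisq(nu_e)`.  The sampler loops over the full conditionals: `g | ELSE ~
#' N(g_hat, B sigma2_e)` with `B = G(G + I lambda)^{-1}` at the current
#' `lambda = sigma2_e / sigma2_g` (the singular-safe representation), and
#' the variances from their scaled inverse chi-square conditionals.  All
#' multivariate-normal draws reuse a single eigendecomposition of `G`; for
#' singular `G` the quadratic form `g' G^{-1} g` is evaluated on the
#' positive-eigenvalue subspace with degrees of freedom `rank(G) + nu_g`.
#'
#' @param y phenotype vector (centered).
#' @param G n x n symmetric PSD relationship matrix.
#' @param priors list with `S_g2`, `nu_g`, `S_e2`, `nu_e` (`nu > 0`).
#' @param S retained samples after burn-in/thinning.
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every `thin`-th draw (default 1).
#' @param seed integer seed.
#' @return `"posterior_samples"` object as for [direct_gblup_sampler()].
#' @export
gibbs_bayesian_gblup <- function(y, G, priors, S, burn_in = 2000, thin = 1,
                                 seed = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n, S >= 1, burn_in >= 0, thin >= 1)
  stopifnot(all(c("S_g2", "nu_g", "S_e2", "nu_e") %in% names(priors)))
  if (priors$nu_g <= 0 || priors$nu_e <= 0) stop("prior df must be > 0")
  if (!is.null(seed)) set.seed(seed)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("G is not positive semidefinite")
  d <- pmax(eg$values, 0)
  pos <- d > 1e-10 * max(d)
  r <- sum(pos)
  U <- eg$vectors
  uy <- drop(crossprod(U, y))

  # start: g = 0, variances at prior modes of the scaled inv-chi-square
  s2g <- priors$S_g2 * priors$nu_g / (priors$nu_g + 2)
  s2e <- priors$S_e2 * priors$nu_e / (priors$nu_e + 2)
  u <- numeric(n)                            # g in eigen coordinates

  total <- burn_in + S * thin
  g_draws <- matrix(NA_real_, S, n)
  s2e_draws <- s2g_draws <- numeric(S)
  kept <- 0L
  for (it in seq_len(total)) {
    lam <- s2e / s2g
    f <- d / (d + lam)
    # g | ELSE: mean U f uy, cov U diag(f) U' s2e; sample in eigen coords
    u <- f * uy + sqrt(f * s2e) * stats::rnorm(n)
    # sigma2_g | ELSE on the positive subspace: g'G^-1 g = sum u_k^2/d_k
    qg <- sum(u[pos]^2 / d[pos])
    s2g <- (qg + priors$S_g2 * priors$nu_g) /
      stats::rchisq(1L, df = r + priors$nu_g)
    g <- drop(U %*% u)
    sse <- sum((y - g)^2)
    s2e <- (sse + priors$S_e2 * priors$nu_e) /
      stats::rchisq(1L, df = n + priors$nu_e)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      g_draws[kept, ] <- g
      s2g_draws[kept] <- s2g
      s2e_draws[kept] <- s2e
    }
  }
  structure(list(g_draws = g_draws, sigma2_e_draws = s2e_draws,
                 sigma2_g_draws = s2g_draws, g_hat = colMeans(g_draws),
                 meta = list(sampler = "gibbs", S = S, seed = seed,
                             burn_in = burn_in, thin = thin,
                             priors = priors)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples (%s): S = %d draws, n = %d\n",
              x$meta$sampler, nrow(x$g_draws), ncol(x$g_draws)))
  cat(sprintf("  mean sigma2_e = %.4g, mean sigma2_g = %.4g\n",
              mean(x$sigma2_e_draws), mean(x$sigma2_g_draws)))
  invisible(x)
}

#' Importance-sampling weights for held-out prediction
#'
#' Converts full-data posterior draws into weights targeting the posterior
#' without the test cases.  The raw log-ratio of draw `s` is the negative
#' log-likelihood the held-out data confer on that draw,
#' `log r_s = sum_j [ (y_j - mu_j(s))^2 / (2 sigma2_e(s)) + log(2 pi
#' sigma2_e(s))/2 ]`, so draws to which the held-out phenotypes give little
#' likelihood receive large weight.  Normalization is done in log space via
#' log-sum-exp; the effective sample size is `1 / sum(w^2)`.
#'
#' The predictor contract is sampler-agnostic: `mu` contains the per-draw
#' predicted means of the test cases (`x_j' beta(s)` for marker-regression
#' samplers, `g_j(s)` for GBLUP samplers).
#'
#' @param mu S x d matrix (or length-S vector for d = 1) of per-draw
#'   predicted means for the test cases.
#' @param y_test the d held-out phenotypes.
#' @param sigma2_e length-S vector of per-draw residual variances, or a
#'   scalar when variances are known.
#' @return Object of class `"is_weights"`: `log_raw`, `w` (normalized,
#'   summing to 1), `s_eff`, `scheme = "IS"`.
#' @export
is_weights <- function(mu, y_test, sigma2_e) {
  mu <- as.matrix(mu)
  d <- ncol(mu); S <- nrow(mu)
  y_test <- as.numeric(y_test)
  stopifnot(length(y_test) == d)
  if (length(sigma2_e) == 1L) sigma2_e <- rep(sigma2_e, S)
  stopifnot(length(sigma2_e) == S)
  if (any(sigma2_e <= 0)) stop("sigma2_e draws must be > 0")
  sq <- sweep(mu, 2L, y_test, "-")^2
  log_raw <- rowSums(sq) / (2 * sigma2_e) +
    (d / 2) * log(2 * pi * sigma2_e)
  if (all(!is.finite(log_raw))) stop("all log weights are non-finite")
  m <- max(log_raw)
  w <- exp(log_raw - m)
  w <- w / sum(w)
  new_is_weights(log_raw, w, "IS")
}

new_is_weights <- function(log_raw, w, scheme) {
  structure(list(log_raw = log_raw, w = w, s_eff = 1 / sum(w^2),
                 scheme = scheme),
            class = "is_weights")
}

#' @export
print.is_weights <- function(x, ...) {
  cat(sprintf("%s weights: S = %d, S_eff = %.1f, max weight = %.4g\n",
              x$scheme, length(x$w), x$s_eff, max(x$w)))
  invisible(x)
}

#' Truncated importance sampling (TIS) weights
#'
#' Caps large importance ratios to stabilize the estimator at the cost of
#' some bias.  The default rule caps the normalized weights at
#' `sqrt(S) x` their mean; the `"S_mean"` rule (`S x` mean) is also provided
#' but is algebraically inert for raw ratios, since every ratio satisfies
#' `r_s <= sum(r) = S x mean(r)` — it can only ever bind through repeated
#' application to renormalized weights.  After capping, weights are
#' renormalized and the effective sample size recomputed; TIS `S_eff` is
#' never below the IS `S_eff`.
#'
#' @param weights an `"is_weights"` object.
#' @param rule `"sqrtS_mean"` (default), `"S_mean"`, or `"custom"`.
#' @param tau explicit cap on the normalized weights when `rule = "custom"`.
#' @return a new `"is_weights"` object with `scheme = "TIS"`.
#' @export
tis_truncate <- function(weights, rule = c("sqrtS_mean", "S_mean", "custom"),
                         tau = NULL) {
  stopifnot(inherits(weights, "is_weights"))
  rule <- match.arg(rule)
  w <- weights$w
  S <- length(w)
  cap <- switch(rule,
                sqrtS_mean = mean(w) * sqrt(S),
                S_mean = mean(w) * S,
                custom = tau)
  if (is.null(cap) || cap <= 0) stop("truncation threshold must be > 0")
  w2 <- pmin(w, cap)
  w2 <- w2 / sum(w2)
  new_is_weights(weights$log_raw, w2, "TIS")
}

#' Sampling-importance-resampling (weighted bootstrap) of posterior draws
#'
#' Resamples `S` draws with replacement with probability proportional to the
#' importance weights; averaging the resampled draws estimates the held-out
#' posterior mean.
#'
#' @param samples a `"posterior_samples"` object.
#' @param weights an `"is_weights"` object computed for these samples.
#' @param seed integer seed.
#' @return a `"posterior_samples"` object of resampled draws (element
#'   `resample_index` records the chosen indices).
#' @export
sir_resample <- function(samples, weights, seed = NULL) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(weights, "is_weights"))
  S <- nrow(samples$g_draws)
  stopifnot(length(weights$w) == S)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(S, S, replace = TRUE, prob = weights$w)
  out <- samples
  out$g_draws <- samples$g_draws[idx, , drop = FALSE]
  out$sigma2_e_draws <- samples$sigma2_e_draws[idx]
  out$sigma2_g_draws <- samples$sigma2_g_draws[idx]
  out$resample_index <- idx
  out$meta$sampler <- paste0(samples$meta$sampler, "+SIR")
  out
}

#' Held-out predictive mean from weighted posterior draws
#'
#' Rao-Blackwellized Monte Carlo estimate of the predictive mean of the test
#' cases: `E(y_test | y_train) = sum_s w_s mu_test(s)` (`mode = "weighted"`),
#' or the average of SIR-resampled predictors (`mode = "sir"`).
#'
#' @param mu S x d matrix (or length-S vector) of per-draw predicted means.
#' @param weights an `"is_weights"` object.
#' @param mode `"weighted"` (default) or `"sir"`.
#' @param seed seed for the SIR resampling step.
#' @return length-d vector of predictive means, with attribute `"mc_se"`
#'   giving the weighted-estimator Monte Carlo standard errors.
#' @export
bayes_heldout_predict <- function(mu, weights, mode = c("weighted", "sir"),
                                  seed = NULL) {
  mu <- as.matrix(mu)
  mode <- match.arg(mode)
  w <- weights$w
  stopifnot(nrow(mu) == length(w))
  est <- drop(crossprod(mu, w))
  mc_se <- sqrt(drop(crossprod(sweep(mu, 2L, est, "-")^2, w^2)))
  if (mode == "sir") {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample.int(length(w), length(w), replace = TRUE, prob = w)
    est <- colMeans(mu[idx, , drop = FALSE])
  }
  attr(est, "mc_se") <- mc_se
  est
}

#' Bayesian leave-one-out CV from one posterior run
#'
#' Loops the importance-sampling machinery over every case: per case `i`,
#' weights are computed from the draws' predicted means for `i` and the
#' held-out predictive mean is the weighted average.  Returns the full CV
#' result plus per-case effective sample sizes (IS and, optionally, TIS).
#'
#' @param samples a `"posterior_samples"` object whose `g_draws` columns are
#'   the per-case predicted means.
#' @param y phenotype vector (same order as the columns of `g_draws`).
#' @param tis if TRUE, also apply [tis_truncate()] and report TIS results.
#' @param tis_rule truncation rule passed to [tis_truncate()].
#' @return a [cv_result] with extra components `s_eff` (IS), and when
#'   `tis = TRUE`, `predictions_tis` and `s_eff_tis`.
#' @export
bayes_loo <- function(samples, y, tis = FALSE, tis_rule = "sqrtS_mean") {
  stopifnot(inherits(samples, "posterior_samples"))
  y <- as.numeric(y)
  n <- ncol(samples$g_draws)
  stopifnot(length(y) == n)
  pred <- s_eff <- numeric(n)
  pred_t <- s_eff_t <- if (tis) numeric(n) else NULL
  for (i in seq_len(n)) {
    mu <- samples$g_draws[, i]
    wi <- is_weights(mu, y[i], samples$sigma2_e_draws)
    pred[i] <- sum(wi$w * mu)
    s_eff[i] <- wi$s_eff
    if (tis) {
      wt <- tis_truncate(wi, rule = tis_rule)
      pred_t[i] <- sum(wt$w * mu)
      s_eff_t[i] <- wt$s_eff
    }
  }
  extra <- list(s_eff = s_eff)
  if (tis) {
    extra$predictions_tis <- pred_t
    extra$s_eff_tis <- s_eff_t
  }
  new_cv_result(pred, y, "Bayes IS LOO", extra = extra)
}
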
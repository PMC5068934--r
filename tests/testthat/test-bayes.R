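test_that("importance weights: hand-computed two-draw case, uniform and
          degenerate limits, shift invariance", {
  # two draws with hand-computed Gaussian likelihoods
  y <- 0.3; s2 <- 0.5
  mu <- c(0.1, 1.4)
  L <- stats::dnorm(y, mu, sqrt(s2))
  w <- is_weights(mu, y, s2)
  expect_equal(w$w, (1 / L) / sum(1 / L), tolerance = 1e-12)
  expect_equal(sum(w$w), 1, tolerance = 1e-12)

  # S = 1 and identical draws
  w1 <- is_weights(matrix(0.2), 0.5, 1)
  expect_equal(w1$w, 1)
  expect_equal(w1$s_eff, 1)
  wS <- is_weights(rep(0.2, 50), 0.5, 1)
  expect_equal(wS$w, rep(1 / 50, 50), tolerance = 1e-14)
  expect_equal(wS$s_eff, 50, tolerance = 1e-10)

  # normalized weights invariant to constant shifts of the log ratios
  # (d-plet weights equal the product construction by log-additivity)
  mu2 <- cbind(rnorm(20), rnorm(20))
  wd <- is_weights(mu2, c(0.1, -0.2), 0.8)
  wa <- is_weights(mu2[, 1], 0.1, 0.8)
  wb <- is_weights(mu2[, 2], -0.2, 0.8)
  raw <- wa$log_raw + wb$log_raw
  expect_equal(wd$w, exp(raw - max(raw)) / sum(exp(raw - max(raw))),
               tolerance = 1e-12)

  expect_error(is_weights(rnorm(5), 0, -1), "sigma2_e")
})

test_that("effective sample size identities (both algebraic forms)", {
  set.seed(71)
  for (r in 1:50) {
    w <- stats::rexp(100)
    w <- w / sum(w)
    s_eff <- 1 / sum(w^2)
    # 1/sum(w^2) = 1/(S (Var + mean^2)) with the population variance
    S <- length(w)
    expect_equal(s_eff, 1 / (S * (mean(w^2) - mean(w)^2 + mean(w)^2)),
                 tolerance = 1e-10)
    expect_true(s_eff >= 1 - 1e-10 && s_eff <= S + 1e-10)
  }
  # one-hot weights
  w <- c(1, rep(0, 9))
  expect_equal(1 / sum(w^2), 1)
})

test_that("TIS truncation: uniform unchanged, dominant weight capped,
          S_mean rule inert on raw ratios, s_eff never decreases", {
  u <- is_weights(rep(1, 40), 0, 1)          # uniform
  expect_equal(tis_truncate(u)$w, u$w, tolerance = 1e-14)

  # one dominant raw ratio 1000x the rest, S = 100
  lr <- c(log(1000), rep(0, 99))
  w <- exp(lr) / sum(exp(lr))
  obj <- structure(list(log_raw = lr, w = w, s_eff = 1 / sum(w^2),
                        scheme = "IS"), class = "is_weights")
  tt <- tis_truncate(obj)                    # cap = mean(w) * sqrt(100) = 10x mean
  cap <- mean(w) * 10
  expect_equal(tt$w, pmin(w, cap) / sum(pmin(w, cap)), tolerance = 1e-14)
  expect_gt(tt$s_eff, obj$s_eff)
  # S_mean cap can never bind: every normalized weight <= 1 = S * mean
  expect_equal(tis_truncate(obj, rule = "S_mean")$w, obj$w,
               tolerance = 1e-14)

  set.seed(72)
  for (r in 1:100) {
    lw <- stats::rnorm(64, sd = 3)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    o <- structure(list(log_raw = lw, w = w, s_eff = 1 / sum(w^2),
                        scheme = "IS"), class = "is_weights")
    expect_gte(tis_truncate(o)$s_eff, o$s_eff - 1e-10)
  }
})

test_that("SIR resampling: one-hot and uniform limits, mean agreement", {
  set.seed(73)
  n <- 5; S <- 4000
  smp <- direct_gblup_sampler(rnorm(n), diag(n), 1, 1, S, seed = 74)
  onehot <- structure(list(log_raw = c(10, rep(-10, S - 1)),
                           w = c(1, rep(0, S - 1)), s_eff = 1,
                           scheme = "IS"), class = "is_weights")
  rs <- sir_resample(smp, onehot, seed = 75)
  expect_true(all(rs$resample_index == 1L))

  uw <- structure(list(log_raw = rep(0, S), w = rep(1 / S, S),
                       s_eff = S, scheme = "IS"), class = "is_weights")
  rs2 <- sir_resample(smp, uw, seed = 76)
  # ordinary bootstrap: resampled mean close to the plain mean
  expect_lt(max(abs(colMeans(rs2$g_draws) - colMeans(smp$g_draws))),
            4 * max(apply(smp$g_draws, 2, sd)) / sqrt(S))
})

test_that("direct sampler is reproducible and Monte-Carlo consistent", {
  set.seed(77)
  K <- random_psd(10, 15)
  y <- rnorm(10)
  a <- direct_gblup_sampler(y, K, 2, 0.8, S = 5, seed = 78)
  b <- direct_gblup_sampler(y, K, 2, 0.8, S = 5, seed = 78)
  expect_identical(a$g_draws, b$g_draws)

  big <- direct_gblup_sampler(y, K, 2, 0.8, S = 50000, seed = 79)
  H <- K %*% solve(K + diag(2, 10))
  gh <- drop(H %*% y)
  expect_equal(big$g_hat, gh, tolerance = 1e-10)
  sds <- sqrt(diag(H) * 0.8)
  expect_true(all(abs(colMeans(big$g_draws) - gh) <=
                    4 * sds / sqrt(50000) + 1e-12))
  # sample covariance approaches H * sigma2_e
  expect_lt(max(abs(cov(big$g_draws) - H * 0.8)), 0.02)
})

test_that("Gibbs sampler recovers generating variances and GBLUP mean", {
  X <- center(simulate_genotypes(100, 150, coding = "additive_m101",
                                 seed = 81))
  G <- linear_kernel(X, scale = "p")
  # generate directly under g ~ N(0, G * s2g) with s2g = 1, s2e = 1
  set.seed(83)
  eg <- eigen(G, symmetric = TRUE)
  g_true <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(100)))
  y <- g_true + rnorm(100)
  priors <- list(S_g2 = 1, nu_g = 4, S_e2 = 1, nu_e = 4)
  post <- gibbs_bayesian_gblup(y, G, priors, S = 1500, burn_in = 500,
                               seed = 84)
  pm_g <- mean(post$sigma2_g_draws); sd_g <- sd(post$sigma2_g_draws)
  pm_e <- mean(post$sigma2_e_draws); sd_e <- sd(post$sigma2_e_draws)
  expect_lt(abs(pm_g - 1), 3 * sd_g)
  expect_lt(abs(pm_e - 1), 3 * sd_e)
  # posterior mean of g close to GBLUP at the posterior-mean lambda
  lam_hat <- pm_e / pm_g
  gh <- fitted(kernel_fit(G, y, lam_hat))
  expect_gt(cor(post$g_hat, gh), 0.99)
})

test_that("weighted IS LOO predictive means match the closed-form held-out
          posterior means; SIR agrees with weighting", {
  Xg <- center(simulate_genotypes(15, 40, seed = 91))
  G <- tcrossprod(Xg)
  y <- center(simulate_phenotypes(Xg, 0.02, 1, seed = 92)$y)
  lam <- 30; s2e <- 1
  smp <- direct_gblup_sampler(y, G, lam, s2e, S = 40000, seed = 93)
  bl <- bayes_loo(smp, y, tis = TRUE)
  closed <- loo(kernel_fit(G, y, lam))$predictions
  for (i in seq_along(y)) {
    wi <- is_weights(smp$g_draws[, i], y[i], s2e)
    se <- attr(bayes_heldout_predict(smp$g_draws[, i], wi), "mc_se")
    expect_lt(abs(bl$predictions[i] - closed[i]), 3 * se + 1e-8)
  }
  expect_true(all(bl$s_eff_tis >= bl$s_eff - 1e-9))
  # SIR route agrees with direct weighting within Monte-Carlo error
  i <- 7
  wi <- is_weights(smp$g_draws[, i], y[i], s2e)
  pw <- bayes_heldout_predict(smp$g_draws[, i], wi)
  ps <- bayes_heldout_predict(smp$g_draws[, i], wi, mode = "sir", seed = 94)
  se_sir <- sd(smp$g_draws[, i]) / sqrt(wi$s_eff)
  expect_lt(abs(drop(ps) - drop(pw)), 4 * se_sir)
  # S = 1 returns that draw's predictor
  one <- is_weights(matrix(smp$g_draws[1, i]), y[i], s2e)
  expect_equal(drop(bayes_heldout_predict(matrix(smp$g_draws[1, i]), one)),
               smp$g_draws[1, i], ignore_attr = TRUE)
})
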
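---
title: "Cross-validation from a single fit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validation from a single fit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oneshotcv)
```

## The problem

Genome-enabled prediction compares models by cross-validation (CV): hold
out one or several phenotyped lines, train on the rest, predict the
held-out phenotypes, and score the predictive mean squared error (PMSE).
Done naively, a leave-one-out (LOO) CV on $n$ lines requires $n$ model
fits, and replicated leave-$d$-out layouts multiply that further.  For
every *linear smoother* this is unnecessary: all held-out predictions are
exact functionals of the single full-data fit.  This package implements
those closed forms for four predictors, and an importance-sampling
analogue for Bayesian models fit by Monte Carlo sampling.

## Exact CV for linear smoothers

### Ordinary least squares

With $y = X\beta + e$, $e \sim N(0, I\sigma^2_e)$ and full-rank $X$
($p < n$), the fitted residual $\hat e_i$ and leverage
$h_{ii} = x_i'(X'X)^{-1}x_i$ give the held-out residual and coefficients

$$y_i - x_i'\hat\beta_{(-i)} = \frac{\hat e_i}{1-h_{ii}}, \qquad
\hat\beta_{(-i)} = \hat\beta - \frac{(X'X)^{-1}x_i \hat e_i}{1-h_{ii}},$$

and for a test set of $d$ rows, with $H_d = X_d (X'X)^{-1} X_d'$ the test
block of the hat matrix, the prediction errors are
$(I-H_d)^{-1}\hat e_d$ and $\mathrm{PMSE}(d) = \hat e_d'(I-H_d)^{-2}\hat
e_d / d$.  When $d$ approaches $n - p$ the matrix $I - H_d$ can become
singular; `leave_d_out()` then switches to the Moore–Penrose generalized
inverse and sets a `rank_deficient` flag — the predictions themselves are
invariant to the choice of generalized inverse, which the test suite
checks rather than assumes.

Expected (rather than realized) PMSE is available in closed form too:
$E[\mathrm{PMSE}(d)] = \{\delta_d'(I-H_d)^{-2}\delta_d +
\mathrm{tr}[(I-H_d)^{-1}]\sigma^2_e\}/d$, with $\delta$ the prediction
bias.  `expected_pmse_ols()` evaluates it; the test suite verifies it
against Monte-Carlo averages of realized PMSE over 20,000 simulated
response vectors.

### Ridge regression / BLUP of marker effects

Treating marker effects as random, $\beta \sim N(0, I\sigma^2_\beta)$,
gives the shrunken estimator $\beta_r = (X'X + I\lambda)^{-1}X'y$ with
$\lambda = \sigma^2_e/\sigma^2_\beta$ *held fixed across folds*.  The same
downdate identities hold with the ridge leverage $h^r_{ii} =
x_i'(X'X+I\lambda)^{-1}x_i$, which is exactly the $i$-th diagonal of the
smoother $G(G+I\lambda)^{-1}$, $G = XX'$.  All computations therefore run
through one $n \times n$ eigendecomposition — for marker panels with
$p \gg n$ the $p \times p$ system is never formed, and the coefficient
downdates use $C^{-1}X' = X'(XX'+I\lambda)^{-1}$.

The fixed-$\lambda$ assumption is the operating assumption of the whole
shortcut: removing one line from a reasonably sized training set moves
the ML estimate of $\lambda$ by little (the package lets you check this
on your own data by re-estimating per fold with
`ml_variance_components()` on training subsets).  Leave-$d$-out with a
large $d$, however, shifts $\lambda$ substantially, and the shortcut
then answers "CV at the full-data $\lambda$", not "CV with re-estimated
shrinkage" — an intentional, documented semantics.

### GBLUP and RKHS regression

For a kernel $K$ (genomic relationship $XX'$, or a Gaussian kernel), the
fit is $\hat g = K(K+I\lambda)^{-1} y$, a singular-safe form that never
requires $K^{-1}$.  The classical mixed-model notation writes this
smoother as $C^{-1} = (I + K^{-1}\lambda)^{-1}$; we evaluate it
eigendecomposition-wise so rank-deficient kernels are handled
transparently.  LOO and leave-$d$-out use the smoother's diagonal $c_{ii}$
and test blocks $C_{dd}$:

$$\tilde g_d = (I - C_{dd})^{-1}(\hat g_d - C_{dd} y_d).$$

For $\lambda > 0$ the smoother's eigenvalues lie in $[0, 1)$, so these
systems are always nonsingular.  With $K = XX'$ (scale constant $c = 1$)
the results coincide with the ridge route to machine precision — an
identity the test suite enforces at $10^{-9}$ relative error, together
with brute-force refit oracles for all four methods.

### Two-kernel models

`bikernel_fit()` fits $y = g_P + g_M + e$ with independent kernel priors
(e.g. pedigree + markers), solving the coupled equations
$\hat g_P = B_P(y - \hat g_M)$, $\hat g_M = B_M(y - \hat g_P)$,
$B = K(K+I\lambda)^{-1}$, as one linear system.  For LOO two update
rules present themselves, and they are *not* equivalent:

* **Uncoupled component equations** (`method = "component"`): update each
  component holding the other fixed at its full-data value,
  $\tilde g_{i,P} = [\hat g_{i,P} - c_{P,ii}(y_i - \hat g_{i,M})] /
  (1 - c_{P,ii})$ with $c_P$ the *single-kernel* smoother diagonal.
  This is exact when one component vanishes, but against a brute-force
  two-kernel refit oracle it deviates by up to a few tenths of the
  prediction standard deviation on random instances: removing case $i$
  perturbs *both* components, and the cross-term is not negligible.
* **Combined smoother** (`method = "exact"`, the default): the summed
  prediction $\hat g_P + \hat g_M = Sy$ is itself a penalized
  least-squares smoother, so the leave-one-out lemma applies to $S$
  directly: $\tilde y_i = (\hat y_i - s_{ii} y_i)/(1 - s_{ii})$, and the
  per-component held-out values follow from the component smoother
  diagonals $S_{P,ii}$, $S_{M,ii}$.  This matches the refit oracle to
  $10^{-14}$.

Both are exposed; the test suite records both tolerance tiers.

## Maximum likelihood variance components

`ml_variance_components()` maximizes the marginal likelihood of
$y \sim N(0, G\sigma^2_g + I\sigma^2_e)$.  One eigendecomposition
$G = UDU'$ reduces every likelihood evaluation to $O(n)$;
the optimizer works on $(\log\sigma^2_g, \log\sigma^2_e)$ (positivity by
construction) with BFGS from three deterministic starts splitting
$\mathrm{var}(y)$ 10/90, 50/50 and 90/10 between the components, because
convergence of a single start to the global maximum is not guaranteed.
Eigenvalues below $-10^{-8}\times$ the largest are an error (not PSD);
small negatives within tolerance are clipped to zero.  A flat spectrum
(e.g. $G = I$) identifies only $\sigma^2_g + \sigma^2_e$; this is
detected and reported as `converged = FALSE` with
`identifiable = FALSE` rather than returning an arbitrary point on the
ridge.  ML (not REML) is used deliberately: the centered-phenotype
convention loses one degree of freedom, which is immaterial at the
sample sizes this package targets.

Model complexity at shrinkage $\lambda$ is
$p_{\mathrm{eff}} = \mathrm{tr}[K(K+I\lambda)^{-1}] = \sum_k
d_k/(d_k+\lambda)$, and $\nu_e = n - p_{\mathrm{eff}}$; a whole
$\lambda$ grid reuses one set of eigenvalues
(`effective_parameters(X, lambda_grid)`).

## Bayesian CV by importance sampling

A Bayesian model fit once on all data yields draws $\theta^{(s)}$.
Held-out predictive means for a test set are recovered by weighting each
draw by the reciprocal of the likelihood the held-out data confer on it:

$$w_s \propto 1/p(y_{\mathrm{test}} \mid \theta^{(s)}), \qquad
\hat E(y_{\mathrm{test}} \mid y_{\mathrm{train}}) = \sum_s w_s
\mu_{\mathrm{test}}(\theta^{(s)}).$$

All weight arithmetic happens in log space with log-sum-exp
normalization: the raw ratio $\exp[(y_i - g_i^{(s)})^2 / 2\sigma^2_e]$
overflows double precision at moderate residuals, while normalized
weights are invariant to any constant shift of the log ratios (a tested
property).  The per-case effective sample size $S_{\mathrm{eff}} =
1/\sum_s w_s^2$ diagnoses weight degeneracy.

Truncated importance sampling (`tis_truncate()`) caps large weights.
The textbook cap $\min(r_s, S\bar r)$ applied to raw ratios is
algebraically inert — every ratio satisfies $r_s \le \sum_s r_s = S \bar
r$ — so the package's default caps the *normalized* weights at
$\sqrt{S}$ times their mean, which genuinely truncates and always
increases $S_{\mathrm{eff}}$; the inert rule is still available for
comparison.  SIR (`sir_resample()`) provides the weighted-bootstrap
alternative to direct weighting.

Two samplers are included: `direct_gblup_sampler()` draws independently
from the exact posterior $N(\hat g, K(K+I\lambda)^{-1}\sigma^2_e)$ when
variances are known (no MCMC needed), and `gibbs_bayesian_gblup()` runs
the two-variance hierarchical model with scaled inverse chi-square
priors.  For singular $G$ the quadratic form $g'G^{-1}g$ in the
$\sigma^2_g$ conditional is evaluated on the positive-eigenvalue
subspace with $\mathrm{rank}(G) + \nu_g$ degrees of freedom, which
coincides with the usual $n + \nu_g$ when $G$ has full rank.  The
central validation is conjugate: on a known-variance Gaussian instance
the IS LOO predictive means must match the closed-form held-out
posterior means (which are exactly the `kernel_fit` LOO predictions)
within Monte-Carlo error — the acceptance suite runs this at $n = 20$,
$S = 10^5$, case by case.

## Synthetic data: what it emulates, what it does not

`simulate_genotypes()` draws independent biallelic loci — binary
presence/absence markers (Bernoulli with per-locus frequency uniform in
the MAF range, default 0.05–0.5) or additive $\{-1,0,1\}$ codes —
and `simulate_phenotypes()` generates $y = X\beta + e$ with
$\beta \sim N(0, I\sigma^2_\beta)$, $e \sim N(0, I\sigma^2_e)$.  This is
exactly the generating model the CV formulas presuppose, which is the
point: the generators are the verification backbone, not a population
simulator.  They do **not** produce linkage disequilibrium, family or
population structure, or multi-environment phenotypes; passing tests
demonstrate correctness of the algebra and calibration of the
estimators under the model, not robustness to structured real data.
Real marker panels concentrate kernel eigenvalues much more strongly
than independent loci do, so quantities such as
$p_{\mathrm{eff}}$ are systematically larger on simulated panels of the
same size.

The wheat-scale conditions used by `scripts/acceptance.R` are $n = 599$
lines, $p = 1279$ binary markers, $\lambda = 190$ and $\sigma^2_e =
0.54$ (so $\sigma^2_\beta = 0.54/190$), with the OLS experiment using an
intercept plus markers 301–500 by file order, 300 random layouts per
$d$, and $S = 15{,}000$ posterior draws for the Bayesian LOO.  Variance
recovery is checked at $n = 400$, $p = 800$, $\lambda = 200$ with
additive coding over 20 seeds (median within ±25%); the additive code
gives per-locus variance $2f(1-f)$, roughly doubling the signal of the
binary code at equal $\sigma^2_\beta$ and making the variance ratio
well-identified at that sample size.

## Numerical choices

* All smoothers, fits and complexity traces run off symmetric
  eigendecompositions; eigenvalues below $10^{-12}\times$ the largest
  are set to exactly zero, so numerically rank-deficient Gram matrices
  behave like their exact-rank counterparts even at tiny $\lambda$.
* For $p \le n$ the ridge coefficient path solves the primal
  $p \times p$ system (numerically safer near the OLS limit); for
  $p > n$ the dual $n \times n$ route is used; both are tested to agree.
* Degenerate inputs error loudly: rank-deficient $X$ in the OLS path
  (no silent pseudo-inverse), leverage $\ge 1 - 10^{-12}$
  (self-determined case), non-PSD kernels, weights with all-non-finite
  log ratios.
* With-replacement CV layouts may repeat an index inside one test set;
  engines deduplicate indices for training removal and score every
  sampled instance, so PMSE reflects the sampled multiset.
* Centering is explicit (`center()`), never implicit, and stores the
  removed means; the `{0,1}` vs `{-1,0,1}` coding distinction vanishes
  after centering.

## Problem sizes and runtime

The test suite runs entirely on synthetic instances: the refit-oracle
property sweep uses 250 random instances at $n \le 60$, $p \le 120$,
$d \le 8$, $\lambda \in \{0.1, 1, 10, 190\}$; the Monte-Carlo
expected-PMSE checks use 20,000 replicate response vectors on fixed
small designs; the full suite completes in well under a minute, and the
acceptance script at wheat scale in a few seconds.

## Known limitations

* The exact shortcuts require fixed $\lambda$; per-fold re-estimation is
  available only as brute force.
* Importance-sampling LOO degrades when the full-data posterior is much
  narrower than the held-out posterior (small per-case
  $S_{\mathrm{eff}}$); TIS trades that variance for bias.  Weight
  smoothing beyond truncation (e.g. fitting a tail distribution to the
  largest ratios) is out of scope.
* Only Gaussian-likelihood samplers ship with the package; the weight
  engine accepts any sampler's draws through the predictor-matrix
  contract.
* No missing-genotype handling: inputs must be complete.
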
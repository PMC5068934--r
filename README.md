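# oneshotcv

Exact cross-validation **from a single model fit** for genome-enabled
prediction.

## The problem

Breeders and quantitative geneticists compare prediction machines —
least squares on selected markers, ridge regression / SNP-BLUP, genomic
BLUP (GBLUP), kernel (RKHS) regression, Bayesian hierarchical models —
by cross-validation: hold lines out of training, predict their
phenotypes, score the predictive mean squared error (PMSE).  Naively, a
leave-one-out (LOO) CV on *n* lines means *n* model fits, and replicated
leave-*d*-out layouts multiply that cost; for MCMC-fitted Bayesian
models it is prohibitive.

For every linear smoother the refits are unnecessary.  With hat value
*h<sub>ii</sub>* = *x<sub>i</sub>′(X′X)<sup>−1</sup>x<sub>i</sub>* and full-data
residual *ê<sub>i</sub>*, the held-out OLS residual is
*ê<sub>i</sub>/(1 − h<sub>ii</sub>)*; for a test set of *d* rows with hat block
*H<sub>d</sub>*, prediction errors are *(I − H<sub>d</sub>)<sup>−1</sup>ê<sub>d</sub>*.
The same identities hold for ridge/BLUP via the smoother
*G(G + Iλ)<sup>−1</sup>* (*G = XX′*, *λ = σ²<sub>e</sub>/σ²<sub>β</sub>*) and
for any PSD kernel *K* via *K(K + Iλ)<sup>−1</sup>* — all singular-safe,
never forming *K<sup>−1</sup>*.  For Bayesian models, one full-data
posterior sample is converted into held-out predictive means by
importance sampling with weights ∝ 1/p(y<sub>test</sub> | θ<sup>(s)</sup>),
with truncated-weight (TIS) and weighted-bootstrap (SIR) variants and
per-case effective sample sizes.

The package provides: `ols_fit()`, `ridge_fit()`, `kernel_fit()`,
`bikernel_fit()` with `loo()` / `leave_d_out()` methods; ML variance
components from one eigendecomposition (`ml_variance_components()`);
model complexity (`effective_parameters()`, `effective_residual_df()`);
kernel construction (`linear_kernel()`, `gaussian_multikernel()`);
influence/leverage diagnostics (`influence_scan()`); Bayesian machinery
(`direct_gblup_sampler()`, `gibbs_bayesian_gblup()`, `is_weights()`,
`tis_truncate()`, `sir_resample()`, `bayes_loo()`); synthetic-data
generators; delimited-text readers/writers and a thin CLI
(`inst/cli/oneshot-cv.R`).

Every shortcut is verified in the test suite against brute-force refit
oracles at 1e−9 relative error.

## Worked example

Simulate a wheat-like panel (binary markers), estimate the shrinkage
ratio by ML, and run LOO plus a replicated leave-10-out layout — all
from one fit:

```r
library(oneshotcv)
X   <- center(simulate_genotypes(300, 800, coding = "binary01", seed = 42))
sim <- simulate_phenotypes(X, sigma2_b = 0.54/190, sigma2_e = 0.54, seed = 43)
y   <- center(sim$y)

vc <- ml_variance_components(y, linear_kernel(X))
vc
#> Marginal ML variance components (n = 300 )
#>   sigma2_g = 0.00460717
#>   sigma2_e = 0.388747
#>   lambda   = 84.3787
#>   log-likelihood = -421.3232  converged: TRUE

fit <- ridge_fit(X, y, vc$lambda)
loo(fit)
#> Cross-validation result (ridge LOO): 300 held-out predictions
#>   PMSE = 0.895133   predictive correlation = 0.3625

lay <- make_cv_layouts(300, d = 10, replicates = 100,
                       replacement = TRUE, seed = 44)
summary(leave_d_out(fit, lay))
#> ridge leave-d-out cross-validation over 1000 cases: PMSE 0.988541, r 0.3163
#> Per-replicate PMSE quantiles:
#>     5%    25%    50%    75%    95%
#> 0.3349 0.6050 0.9340 1.2522 1.8551

effective_parameters(X, vc$lambda)
#> Effective parameters: p_eff = 170.0170, nu_e = 129.9830 (n = 300, lambda = 84.3787)
```

Reading the output: the ML shrinkage ratio λ ≈ 84 says residual variance
is ~84× the per-marker effect variance; at that λ the 800-marker model
spends ~170 effective parameters on 300 observations.  The LOO PMSE
(0.90) exceeds the model's in-sample fit error, as it must, and the
replicated leave-10-out layout shows the spread of PMSE across random
test sets — information a single LOO number hides.  None of this
refitted the model: the 1,000 held-out predictions above come from one
eigendecomposition.

GBLUP is the same computation through the kernel route —
`kernel_fit(linear_kernel(X), y, lambda)` reproduces `X %*% coef(fit)`
exactly — and `bayes_loo(direct_gblup_sampler(...), y)` gives the
importance-sampled Bayesian analogue.

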
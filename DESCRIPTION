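Package: oneshotcv
Title: Exact Cross-Validation from a Single Model Fit for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form leave-one-out and leave-d-out cross-validation for
    least squares, ridge regression (SNP-BLUP), genomic BLUP and reproducing
    kernel Hilbert space regression, computed from one full-data fit via hat
    matrix and smoother-matrix downdate identities.  Includes maximum
    likelihood estimation of variance components through a single
    eigendecomposition, effective model complexity and residual degrees of
    freedom, influence and leverage diagnostics, multi-bandwidth Gaussian
    kernel construction, and Bayesian cross-validation by importance sampling
    (with truncated-weight and sampling-importance-resampling variants) of
    posterior draws from a single Gibbs or direct sampler run.  Synthetic
    marker and phenotype generators with brute-force refit oracles provide
    the verification backbone.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
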
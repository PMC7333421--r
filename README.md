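# cisrrr — coordinate-independent sparse reduced-rank regression

`cisrrr` estimates the coefficient matrix of a multivariate linear model

    Y = X C + E,        Y: n x q responses,  X: n x p predictors,

under the two structural assumptions that make high-dimensional
multi-omics regression tractable: **low rank** (rank(C) = r << min(p, q),
so the responses are driven by a few latent factors) and **row sparsity**
(whole rows of C are zero, removing a predictor from all q response models
simultaneously). The motivating use is integrating genomics with
metabolomics: X holds additively coded SNPs (0/1/2 minor-allele counts),
Y holds standardised log2 metabolite features, and the nonzero rows of C
identify SNPs associated with the metabolome. The package is written for
statisticians and genetic epidemiologists running that kind of analysis,
and for methods work that needs a well-tested reference implementation.

## The estimator

Factor C = B Aᵀ with A a q x r orthonormal basis of the right singular
subspace of C (estimated from the SVD of Y, or of a ridge pilot fit of C).
Given A, B solves the convex **group Dantzig program**

    minimise   Σⱼ ‖bⱼ‖₂
    subject to maxⱼ ‖ Xⱼᵀ (Y A − X B) ‖₁  ≤  τ,

where bⱼ is the j-th row of B and Xⱼ the j-th predictor column. The
objective zeroes whole rows; the constraint bounds the strongest residual
correlation of any predictor. At q = r = 1 this is exactly the classical
Dantzig selector. τ is the sparsity parameter — larger is sparser, and
every τ ≥ τ_max = maxⱼ ‖XⱼᵀYA‖₁ yields B = 0 — and is tuned by K-fold
cross-validation of mean squared prediction error over 20 grid points in
(0, τ_max]; the rank is tuned the same way over r ∈ {1, …, 10}. The
selected row set is invariant to signed permutations of the basis A, hence
"coordinate-independent". The solver is a preconditioned primal-dual
method with a certified duality gap, written in compiled code.

Around the estimator the package provides the full study apparatus: a
simulation engine (AR(1)-correlated designs, row-sparse low-rank signal,
three unit-variance noise families, named RNG substreams), evaluation
metrics (Δ = ‖C − Ĉ‖²_F/(pq), test MSPE, TPR/FPR), bootstrap stability
selection, a replication runner, and a downstream genetic-risk-score /
two-stage Mendelian-randomization pipeline (metabolite QC filter, additive
coding, bootstrapped log-odds GRS weights, BH-screened two-stage screen)
runnable end to end on a synthetic cohort.

## Worked example

Simulate the n > p regime (n = 100, p = q = 25, s = 15 informative rows,
rank 5, signal scale b = 0.4, AR(1) correlation 0.1), tune τ by 5-fold
cross-validation at the true rank, and evaluate against the ground truth:

```r
library(cisrrr)

design <- sim_case(1, b = 0.4, rho = 0.1, seed = 42)
d  <- generate_dataset(design)
cv <- cv_cisrrr(d$X, d$Y, rank = 5, K = 5, seed = 42)
cv
#> 5-fold CV over 20 tau fractions (rank 5)
#>   optimal fraction of tau_max: 0.05 (MSPE 1.6024)
#>   full-data tau_opt: 68.971, 16 predictors selected

test <- generate_test_set(design, n_test = 2000)
evaluate_fit(cv$fit, d$C, d$support, test$X, test$Y)
#>       delta     mspe tpr fpr n_selected
#>  0.01758417 1.435741   1 0.1         16
```

Reading the numbers: cross-validation picks a small fraction of τ_max
(dense end of the grid — appropriate at n = 4p with strong signal). The
fitted model selects 16 predictors covering all 15 truly informative rows
(TPR = 1) with one false positive (FPR = 0.1). The estimation error
Δ = 0.018 is a small fraction of the zero-estimator baseline
‖C‖²_F/(pq) ≈ 0.39 for this draw, and the test MSPE of 1.44 sits close to
the noise floor of 1 (unit-variance noise), against ≈ 11 for predicting
the mean.

Rank selection, stability selection and the downstream pipeline follow the
same pattern; see `?select_rank`, `?bootstrap_stability`,
`?two_stage_mr`, and the methods vignette
(`vignettes/cisrrr-methods.Rmd`) for the model, tuning rules and design
decisions.

A thin command-line interface over the same functions ships at
`inst/cli/cisrrr.R` (subcommands `simulate`, `fit`, `cv`, `stability`,
`evaluate`, `replicate`, `cohort`, `grs`, `mr`; run it with no arguments
for usage).

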
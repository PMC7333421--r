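---
title: "Sparse reduced-rank regression with a group Dantzig program: models, tuning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse reduced-rank regression with a group Dantzig program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisrrr)
```

## The model

`cisrrr` estimates the coefficient matrix of the multivariate linear model

$$Y = X C + E,$$

with $Y$ an $n \times q$ response matrix (for instance standardised log2
metabolite features), $X$ an $n \times p$ predictor matrix (for instance
additively coded SNPs), and $E$ i.i.d. noise. When $p q$ rivals or exceeds
$n$, two structural assumptions make estimation tractable and
interpretable:

* **low rank** — $\operatorname{rank}(C) = r \ll \min(p, q)$, so the $q$
  responses are driven by $r$ latent factors $X B$;
* **row sparsity** — only $s$ of the $p$ predictors have nonzero rows in
  $C$; a zero row removes that predictor from *all* $q$ response models at
  once, which is what turns estimation into variable selection.

Writing $C = B A^\top$ with $A$ a $q \times r$ orthonormal basis of the
right singular subspace of $C$ (equivalently, under the model, of $Y$), and
post-multiplying the model by $A$, estimation reduces to the lower
dimensional regression of $Y A$ on $X$. The nonzero rows of $B$ and $C$
coincide, so row-sparse estimation of $B$ suffices.

## The estimator

Given a subspace estimate $\tilde A$, $B$ solves the convex program

$$\widehat B = \arg\min_B \sum_{j=1}^p \lVert b_j \rVert_2
\quad \text{s.t.} \quad
\max_{1 \le j \le p} \bigl\lVert X_j^\top ( Y \tilde A - X B ) \bigr\rVert_1
\le \tau,$$

a group generalisation of the Dantzig selector: the objective is the group
norm that zeroes whole rows, and the constraint bounds the strongest
remaining correlation between any predictor and the matrix residual. For
$q = r = 1$ both norms collapse to absolute values and the program *is* the
classical Dantzig selector LP (this reduction is tested against an
independent LP solve).

Two properties shape the interface:

* $\tau$ **is the sparsity dial**: larger values admit larger residual
  correlations and hence sparser solutions. At
  $\tau \ge \tau_{\max} = \max_j \lVert X_j^\top Y \tilde A \rVert_1$ the
  zero matrix is feasible and — having objective zero — optimal, so
  `tau_max()` bounds the useful range $(0, \tau_{\max}]$.
* **coordinate independence**: replacing $\tilde A$ by $\tilde A Q$ for a
  signed permutation $Q$ maps the solution to $\widehat B Q$ and leaves the
  selected row set unchanged; only the span of $\tilde A$ matters for
  selection. We assert (and test) invariance for signed permutations, which
  preserve both the row 2-norms of the objective and the inner
  $\ell_1$-norm of the constraint; invariance under arbitrary orthogonal
  $Q$ would additionally require the constraint norm to be rotation
  invariant, which $\ell_1$ is not, so we do not claim it.

## Subspace estimation and refinement

Two initialisations are provided:

* `init = "svd_y"` (default): the top-$r$ right singular vectors of the
  centred $Y$ — the sample estimate of the response's right singular
  subspace;
* `init = "ridge"`: the top-$r$ right singular vectors of the ridge pilot
  estimate $(X^\top X + \sqrt{\log p / n}\, I)^{-1} X^\top Y$. When
  $n < p$, the identity
  $\widehat C = V (R^\top R + \sqrt{\log p / n}\, I)^{-1} R^\top Y$ with
  $X = U D V^\top$, $R = U D$ computes the same matrix through an
  $n \times n$ inversion; both paths are exposed and tested for equality.

`cisrrr()` then alternates (i) the group Dantzig solve for $B$ with (ii) a
subspace update taking the top-$r$ right singular vectors of
$X \widehat C = X B A^\top$, stopping when the *projector* distance
$\lVert A_{\text{new}} A_{\text{new}}^\top - A A^\top \rVert_F$ falls below
`conv_tol` ($10^{-4}$ by default). The projector metric, not a basis
distance, is what respects coordinate independence.

One structural fact deserves emphasis: whenever $X B$ has full column rank
$r$, the row space of $X B A^\top$ is exactly $\operatorname{span}(A)$, so
the subspace update is a fixed point and the procedure converges after a
single refinement pass — the estimator then coincides with the two-stage
procedure (estimate $A$, solve once for $B$). The iteration still earns its
keep as a guard: when the solve returns fewer than $r$ informative
directions (large $\tau$), the rank-degenerate case is detected and the
last consistent $(B, A)$ pair is returned with a `degenerate` flag rather
than a silently rotated basis.

Determinism: every SVD-derived basis is sign-normalised (largest-magnitude
entry of each column positive, ties to the lowest index), so repeated runs
are bit-identical across platforms.

## The solver

The program is solved by a primal-dual hybrid gradient (Chambolle–Pock)
method written in compiled code against the Gram form $S = X^\top X$,
$D = X^\top Y \tilde A$:

* the nonsmooth objective enters through an exact row-wise group
  soft-threshold;
* the constraint enters through its support function; its proximal map is
  an exact row-wise projection onto a shifted $\ell_1$ ball (sort-based);
* steps are diagonally preconditioned by the row sums of $|S|$, with a
  dual-to-primal step ratio of 0.1 — chosen by benchmarking iteration
  counts on Gram matrices of correlated Gaussian designs, where large
  primal steps win;
* progress is accelerated by restarting at the running average of the
  iterates whenever the averaged point halves the convergence merit — the
  ergodic sequence converges fastest on the flat tail of this class of
  methods, and restarting there recovers fast local progress (the device
  behind modern first-order LP solvers);
* convergence is *certified*, not assumed: any dual iterate, rescaled so
  that $\max_j \lVert (S V)_j \rVert_2 \le 1$, yields the lower bound
  $-\sum_j (\langle v_j, d_j\rangle + \tau \lVert v_j \rVert_\infty)$, and
  the solver stops when the relative primal-dual gap and the worst relative
  constraint violation are both under tolerance. Non-convergence within
  `max_iter` is reported in the fit status and raises a warning — never a
  silent zero.

Defaults: `solver_control()` uses a $10^{-7}$ gap and feasibility
tolerance, appropriate for final fits and for comparisons against
independent solvers. Cross-validation sweeps use `cv_solver_control()`
($10^{-4}$ gap): model comparison by prediction error is insensitive to
the last digits of the optimiser, and the looser tolerance keeps a full
$20 \times K \times |r\text{-grid}|$ sweep tractable. A fold/τ cell whose
solve fails is treated as missing in the MSPE average, not as a zero fit.

Selection thresholds row norms of $B$ at $10^{-6}$ relative to the largest
row norm, since first-order (like interior-point) solvers return
near-zeros, never exact zeros.

Centring: $X$ and $Y$ are column-centred before fitting (the model has no
intercept); predictor scaling is off by default, matching simulation
designs whose predictors share unit variance, and available as
`scale_x = TRUE` for data on heterogeneous scales.

## Tuning

**τ.** `cv_cisrrr()` uses K-fold cross-validation (K = 5 by default) of
the mean squared prediction error
$\mathrm{MSPE}(\tau) = \frac{1}{K} \sum_k \lVert X^k \widehat C^k(\tau) -
Y^k \rVert_F^2 / (n_k q)$ over a grid of 20 equally spaced values in
$(0, \tau_{\max}]$. Because $\tau_{\max}$ depends on the training fold and
its initial subspace, absolute τ values are not comparable across folds:
the grid is therefore indexed by *fraction of the fold-specific*
$\tau_{\max}$, giving 20 comparable columns; the winning fraction is
rescaled by the full-data $\tau_{\max}$ for the final fit. Each fold runs
the entire pipeline — centring, initialisation, refinement — on its
training rows only, so no information leaks from held-out rows. Ties in
MSPE resolve to the larger τ (the sparser model).

**Rank.** `select_rank()` scans $r \in \{1, \dots, 10\}$ (clamped to what
$q$ and the fold sizes allow), optimises τ within each rank on shared
folds, and takes $\widehat r = \arg\min_r \mathrm{MSPE}(\tau_{\text{opt}},
r)$, ties to the smallest rank.

**Stability.** `bootstrap_stability()` repeats the whole tuning/fitting
cycle on bootstrap resamples (50 by default), records out-of-bag MSPE, and
reports each predictor's selection frequency; the stable set keeps
predictors selected in at least 90% of replicates. Whether the rank is
re-estimated per replicate is open in the source procedure; the default
re-estimates it (each replicate is a fresh dataset), and `rank =` fixes it
instead.

## The simulation engine

`simulation_design()` / `generate_dataset()` reproduce the generative
structure used throughout the package's evaluation: rows of $X$ drawn from
$N(0, \Sigma)$ with $\Sigma_{ij} = \rho^{|i-j|}$ (sampled exactly through
the Cholesky factor), coefficient matrix
$C = \bigl[\begin{smallmatrix} b\, B_0 B_1 \\ 0 \end{smallmatrix}\bigr]$
with standard normal $B_0$ ($s \times r$) and $B_1$ ($r \times q$), and
i.i.d. unit-variance noise from one of three families — Gaussian,
$\sqrt{3/5}\, t_5$, or the sum of three $U[-1,1]$ variables. The displayed
block form places the informative rows first; `permute_support = TRUE`
scatters them under seed control. Four preset dimension regimes are
provided (`sim_case(1)` through `sim_case(4)`), spanning $n > p = q$ up to
$n < p < q$.

Each dataset draws its components from named substreams of one seed, so
switching the noise family changes only $E$ — paired comparisons across
families see identical designs. Evaluation uses an independently drawn
test set (10,000 rows by convention; tests scale this down) and the
quantities $\Delta = \lVert C - \widehat C \rVert_F^2 / (pq)$, test-set
MSPE, TPR and FPR.

What the generator does *not* emulate: linkage-disequilibrium block
structure, realistic minor-allele-frequency spectra, non-Gaussian predictor
distributions, batch effects, or heteroscedastic noise. Passing tests on
these designs demonstrate correctness of the estimator and its tuning
machinery under the stated statistical structure — not performance on real
genotype data.

## The downstream pipeline

The applied half of the package chains the estimator's output (a stable
SNP set) into a risk analysis, and is runnable end to end on a synthetic
cohort because the motivating cohort data are not public:

* `filter_metabolites()` drops features with more than 50% zeros or a
  raw-scale coefficient of variation of 20% or more, then log2-transforms
  and standardises survivors. The CV is computed over each feature's
  positive cells so the two rules act independently (zeros are judged by
  their own rule); zeros in surviving features receive half the feature's
  smallest positive value before the log, a standard metabolomics
  convention that preserves ordering.
* `grs_weights()` fits single-SNP logistic models of the binary outcome on
  allele counts across bootstrap resamples and combines the per-replicate
  log odds ratios by an inverse-variance weighted mean (the conventional
  meta-analytic default; a plain mean is available via `weighting`),
  excluding separated replicates. `weighted_grs()` forms the per-subject
  score, and `dichotomize_grs()` cuts it strictly above the 75th
  percentile.
* `two_stage_mr()` screens metabolites by regressing each on the score
  (adjusted for age and sex), passing those that clear a
  Benjamini–Hochberg screen at 0.0004, and then fits the outcome on the
  stage-1 fitted values (adjusted for age and sex). Fitted values are
  scaled per SD by default, so stage-2 odds ratios read "per SD of the
  genetically predicted level"; `scale_fitted = FALSE` disables this.
* `generate_cohort()` plants a known SNP → metabolite → outcome chain:
  binomial(2, MAF) genotypes, log2-normal metabolite intensities with
  per-allele shifts, dropout zeros, and a logistic outcome on the
  standardised causal levels plus age and sex. The log2 noise SD defaults
  to 0.15 and per-allele effects to 0.1, sized so that features — including
  genetically driven ones — keep raw-scale CV below the 20% QC cutoff, as
  real post-QC features do. The high/low ASCVD risk label is generated
  directly; computing the clinical risk equations themselves is outside the
  package's scope.

## Problem sizes in the test suite

The automated checks run scaled-down versions of the full study: 10
replicates per design instead of 50, test sets of 500–2,000 rows instead
of 10,000, and 20-replicate bootstraps where the full analysis uses 50.
These sizes keep a full run in minutes while leaving the strongly
identified properties (support recovery, noise calibration, chain
recovery) stable; the rank-selection summary retains visible
seed-to-seed variability at 10 replicates, which is inherent to
cross-validation at $n = 30$ rather than a artefact of scaling down.

## Known limitations

* Sparsity acts on $B$ (predictor selection) only; a row-sparse $A$ for
  response selection is deliberately out of scope.
* The solver is first-order: solutions carry $\sim 10^{-7}$-level gap
  noise rather than interior-point precision; all selection logic uses
  relative thresholds for this reason.
* With $n$ as small as 30, K-fold MSPE is a noisy criterion: the selected
  rank concentrates near the truth but varies across replicates, and with
  only a handful of replicates even the modal rank can move. Reporting the
  full distribution of selected ranks, as the replication runner does, is
  more informative than any single summary.
* The uniqueness of $\widehat B$ holds up to signed permutations of the
  basis; reported factors are made reproducible by the SVD sign convention
  rather than by any claim of full rotational uniqueness.
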
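---
title: "Robust residual screening of CT radiation dose: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust residual screening of CT radiation dose: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctoutliers)
```

## The model

Each CT acquisition is a pair $(x_i, y_i)$: a predictor vector of patient
and protocol metadata and the recorded volume CT dose index CTDIvol (mGy).
The working assumption is that for non-outlying exams the appropriate dose
is approximately linear in the standardized predictors,

$$y_i = \beta_0 + x_i^\top \beta + \varepsilon_i,$$

and that an exam deserving review is one whose recorded dose deviates from
the model prediction by more than three residual standard deviations. The
package fits this plane in two stages — LASSO variable selection, then an
outlier-robust regularized regression (RR) on the selected set — and flags

$$|y_i - \hat y_i| > k \,\hat\sigma_r, \qquad k = 3,$$

with $\hat\sigma_r$ the sample SD of the *training* residuals. Two
comparison detectors are built in: the same rule driven by OLS residuals,
and a global cutoff at mean $+\,3$ SD of the training doses.

## Pre-processing conventions

The pipeline applies, in order: record filters (missing CTDIvol, missing
weight, head exams, more than half the fields missing), indicator encoding
of categoricals with deletion of rare levels (default minimum level count
100 — large enough to remove sparse dummies, small enough to keep real
protocol levels), pruning of columns with $|r| < 0.06$ against CTDIvol,
mean/mode imputation, standardization, and a random 80/20 train/test split
(the split fraction is a package default; any value in $(0,1)$ is
accepted).

Several conventions are deliberate and worth stating because they are
testable:

* **Train-only statistics.** Correlations, imputation values and
  standardization parameters are computed on the training rows and applied
  unchanged to test rows and to new exports (`apply_preprocess()`), so
  held-out data cannot leak into the transform. Operationally the split is
  therefore drawn before the statistics are computed, even though it is the
  last conceptual step of the pipeline.
* **Correlation before imputation**, on pairwise-complete observations:
  imputed values can never manufacture correlation. Columns that are
  constant on the complete pairs have undefined $r$ and are removed.
* **Sample-SD standardization** ($n-1$ denominator): the column $\{0, 2\}$
  becomes $\{-0.707, +0.707\}$, not $\{-1, +1\}$.
* **Mode ties** break to the lexicographically smallest level; rare-level
  rows keep zeros in all sibling indicators; rows with a missing categorical
  get the modal level.
* Both raw numeric columns and indicator columns pass through the
  correlation prune; every drop is logged with a reason code in the
  preprocessing report.

## LASSO selection

`fit_lasso()` minimizes
$\frac{1}{2N}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 + \lambda\|\beta\|_1$
by cyclic coordinate descent with soft-thresholding; the intercept is
unpenalized and handled by centering. Convergence is declared when the
largest coefficient change in a sweep drops below $10^{-7}$; the objective
is recorded after every sweep and is non-increasing by construction (a
property the tests assert). Coefficients above their activation penalty are
*exactly* zero. `lasso_lambda_max()` returns the smallest all-zero penalty
with a relative headroom of $10^{-10}$ so the null model is exact at that
value regardless of floating-point summation order. The default path is 100
log-spaced penalties down to $\lambda_{\max}/10^4$, warm-started.

The selection procedure (`average_lasso_runs()`) runs the LASSO five times,
each on a fresh 80% subsample, with the penalty chosen per run by 5-fold
cross-validated squared error (minimum-error $\lambda$); a fixed $\lambda$
override exists because the selection behaviour at weak penalties differs
materially. Coefficients are averaged arithmetically across runs and
predictors ranked by $|\text{mean}|$; since averaging signed coefficients
and averaging magnitudes can genuinely differ, both are reported. The
headline ranking (`top_predictors()`) excludes indicator columns by
default: one categorical field can expand into many dummies, so mixing them
with raw numeric predictors makes the table hard to read. Dummies are
penalized individually — no group penalty — so individual protocol levels
can be selected.

## The robust regularized regression

No closed form exists for the robust stage, which solves

$$\min_{\beta_0,\beta}\; \frac{1}{N}\sum_i |y_i - \beta_0 - x_i^\top\beta|
  \;+\; \varepsilon\,\|\beta\|_2 .$$

The least-absolute-deviation loss bounds each exam's influence, so a small
contaminated fraction cannot drag the plane; the (unsquared) $\ell_2$-norm
penalty is the regularizer under which this loss arises as a worst-case
robust formulation, and the intercept is never penalized because the dose
scale should not shrink. The program is convex but nonsmooth; it is solved
by ADMM with the splitting $z = y - A\theta$, $w = \beta$, a soft-threshold
prox for $z$, a norm-shrink prox for $w$, and a single cached Cholesky
factor of $A^\top A + S^\top S$ for the quadratic step. The penalty
parameter $\rho$ is adapted by residual balancing (factor 2 when primal and
dual residuals diverge by more than 10x), which the cached factorization
makes free. Internally the objective is scaled to sum-loss form so the prox
step sizes stay on the residual scale at any $N$. The reported slopes come
from the proximal variable $w$, which carries the exact zeros of the
shrink step — at a large enough $\varepsilon$ the fit collapses to the
median-only model exactly.

Default tolerances are $10^{-6}$ (absolute and relative); high-precision
uses (solver cross-checks against a brute-force grid) tighten them to
$10^{-11}$. The penalty $\varepsilon$ can be chosen by 5-fold
cross-validated absolute error over $10^{-4}\dots10^0$ (`penalty_weight =
NULL`); the pipeline default is a fixed weak $\varepsilon = 0.01$, because
on standardized, LASSO-selected designs the robustness comes from the loss,
not the shrinkage, and a fixed weak penalty keeps the end-to-end run
deterministic and fast. OLS is fit by QR, with a minimum-norm SVD fallback
and a warning under rank deficiency.

$R^2$ is defined as $1 - \mathrm{SSR}/(N\,\mathrm{Var}(y))$ with the
*population* variance in the denominator, so predicting the mean gives
exactly 0 and the identity is testable; `residual_sd` is the sample SD of
the residuals, stated explicitly because the 3-SD rule consumes it.

## Detection conventions

The residual rule is **two-sided** (unexpectedly low doses are also worth
review — a systematically over-predicted protocol shows up as negative
residuals), while the cutoff is **one-sided** by construction; both use
strict inequality at the threshold. The training residual SD is frozen when
scoring test or new exams, so contaminated new data cannot widen its own
threshold. A residual SD below `degenerate_sd_tolerance` is an error rather
than a flag-everything run. Review lists rank by $|$residual$|$ (residual
methods) or actual dose (cutoff) with a deterministic tie-break on exam id,
and per-weight-class flag counts are available for committee summaries.

## Validation metrics

`compute_metrics()` reports sensitivity, specificity, PPV, NPV and F1 (the
harmonic mean of PPV and sensitivity) with binomial confidence intervals;
zero denominators yield `NA`, never an error. The default interval is Wald,
$p \pm z\sqrt{p(1-p)/n}$ with $z = \Phi^{-1}((1+\text{level})/2)$, with a
Wilson option for small counts. A `z_value` override is provided because
published clinical tables frequently use the two-sigma rule ($z = 2$) for
"95%" intervals; analysis of the reference operating points this package
reproduces shows their printed intervals follow that convention (Wald with
$z = 1.96$ at full precision rounds the sensitivity lower bound to 0.86,
not the printed 0.85; $z = 2$ reproduces all four printed bounds), so the
reproduction paths in this package pass `z_value = 2`. Presentation
rounding is half away from zero at 2 decimals (`round_half_up()`), since
base R's banker's rounding turns 0.875 into 0.87; full precision is always
retained alongside.

## The synthetic cohort

Real dose records are protected hospital data, so the generator emulates
the structure the method assumes, with defaults fixed once:

* **Patient size**: a five-class truncated-normal mixture (S/M/L/XL/XXL at
  breaks 56.5/79.5/102.5/136.5 kg) with class weights 10.65/45.73/33.38/
  8.98/1.26% and the published class means and SDs; truncation keeps the
  empirical class proportions multinomial. Gender is female with
  probability 0.541; age is drawn $N(60.6, 17.1)$ truncated to $[1, 100]$.
* **Dose model**: CTDIvol $= 15 + \sum_j \beta_j z(x_j) +$ small
  categorical offsets $+\,N(0, 1.5^2)$ mGy, floored at 0.2 mGy, with
  standardized effects 3.49 (tube current), 1.73 (kVp), 1.15 (weight),
  0.66 (collimator width) and 0.37 (reference mAs). Categorical offsets are
  kept below 0.4 mGy so the numeric ranking is recoverable, and head exams
  (8%, later filtered) get a 45 mGy baseline.
* **Decoys**: age, pitch factor, scan length and scan count are generated
  independent of dose, so the $|r| < 0.06$ prune has true positives.
* **Missingness**: each field (including dose and weight, so the record
  filters have work) is masked independently at 2%.
* **Contamination** (1% by default): *mixed*. 60% of the outlier budget is
  concentrated in one designated protocol level at ~45% within-level
  contamination — a systemic protocol misconfiguration, the scenario that
  motivates robust fitting, and the regime where OLS absorbs the shift into
  the level's coefficient and masks the outliers while the LAD fit (below
  its breakdown point) does not. The remaining 40% are sporadic exams
  scattered over the cohort. Inflation factors are heterogeneous — uniform
  on $[1.5, 3]$ (systemic) and $[1.25, 3]$ (sporadic) — because real
  overexposures vary in magnitude and a single fixed factor makes every
  outlier equally easy. A switch generates symmetric (deflating)
  contamination instead.

What the generator does **not** emulate: automatic-exposure-control
feedback and tube physics, multi-phase exam structure, the several-hundred
-column dummy width of a real protocol vocabulary, non-Gaussian dose noise,
and correlated predictors (tube current is independent of weight here;
in reality AEC couples them). Passing tests therefore demonstrate that the
implementation is correct and that the method behaves as designed under its
own assumptions — not that it will achieve any particular operating point
on real hospital data.

## Problem sizes and numerical choices

The simulation studies in the test suite use cohorts of 20,000 exams over
ten seeds for the ranking-recovery and detector-comparison properties, and
smaller cohorts (1,200–2,500) for invariance and smoke tests; these sizes
give comfortable separation of the properties under test while keeping the
suite quick. The acceptance script runs one 20,000-exam end-to-end study.
Other numerical choices collected in one place: coordinate-descent
tolerance $10^{-7}$ on the max coefficient change; ADMM tolerances
$10^{-6}$ with residual-balanced $\rho$; $\lambda_{\max}$ headroom
$10^{-10}$; mode ties lexicographic; dose floor 0.2 mGy; detection
threshold strict; stage seeds derived deterministically from the base seed
(kept below $2^{31}$).

## Known limitations

* The RR stage assumes the LASSO-selected set; whether selection should be
  bypassed (fitting RR on all encoded columns with its own penalty) is
  exposed as an override but not the default.
* The flagged rate is reported on both the full retained cohort and the
  test split; with a frozen training threshold the two can differ by a few
  tenths of a percent.
* No per-protocol stratified thresholds, no streaming scoring, no ROC
  analysis (the method is a fixed-threshold operating point by design).
* LAD robustness degrades as within-stratum contamination approaches 50%;
  a systemic misconfiguration affecting most of a protocol's exams will be
  absorbed by any regression-based detector and is better caught by
  protocol-level audit.
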
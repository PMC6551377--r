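# ctoutliers

Automated detection of CT exams with unwarranted radiation exposure, from
exam metadata alone.

## The problem

Radiation safety committees review CT protocols retrospectively to find
acquisitions where a patient received more radiation than their body habitus
and exam type warrant. The naive screen — flag exams whose volume CT dose
index (CTDIvol) exceeds the historical mean by three standard deviations —
fails in two ways: dose varies legitimately and widely with patient size and
protocol, so a global threshold misses exams that are extreme *for their own
predictors*; and the outliers already present in historical data inflate the
mean and SD, masking future outliers.

`ctoutliers` implements a predictive alternative. A model of the *appropriate*
dose is learned from patient and protocol predictors, and an exam is flagged
when its actual dose deviates from the prediction by more than a multiple of
the residual spread.

## The method

For exam *i* with predictor vector *x<sub>i</sub>* (tube current, kVp, patient
weight, collimator width, reference mAs, scanner/protocol indicators, ...) and
dose *y<sub>i</sub>* = CTDIvol (mGy):

1. **Pre-processing** — discard records with missing CTDIvol or weight, head
   exams, and records with more than half their fields missing; encode
   categoricals as indicators, deleting rare levels; drop predictors with
   |Pearson r| &lt; 0.06 against CTDIvol; impute (mean/mode); standardize;
   split into train/test.
2. **Variable selection** — LASSO, run five times on fresh training
   subsamples with a cross-validated penalty; coefficients are averaged and
   predictors ranked by the magnitude of the averaged coefficient:
   minimize (1/2N) Σ (yᵢ − β₀ − xᵢ'β)² + λ‖β‖₁.
3. **Robust regularized regression (RR)** — on the selected predictors,
   minimize (1/N) Σ |yᵢ − β₀ − xᵢ'β| + ε‖β‖₂.
   The absolute-error loss keeps the fitted plane on the non-outlying exams
   instead of letting gross outliers drag it (the failure mode of ordinary
   least squares); the norm penalty regularizes the slopes. Solved by ADMM.
4. **Detection** — flag exam *i* iff |yᵢ − ŷᵢ| &gt; 3 σ̂, where σ̂ is the SD
   of the training residuals.
5. **Validation** — confusion matrices against a reference labeling, with
   sensitivity, specificity, PPV, NPV, F1 and binomial confidence intervals;
   comparison against an OLS-residual detector and the mean + 3 SD cutoff.

Because real dose records are protected hospital data, the package ships a
synthetic-cohort generator reproducing the statistical structure the method
assumes (patient-size mixture, linear dose model with published effect
magnitudes, missingness, and a ~1% contamination of injected dose outliers,
part systemic, part sporadic), so the whole pipeline is testable end to end.

## Worked example

Validation metrics from 2x2 review counts (tp, fp, fn, tn):

```r
library(ctoutliers)
compute_metrics(confusion_matrix(84, 16, 8, 92), z_value = 2)
#> sensitivity 0.91 [0.85-0.97]  specificity 0.85 [0.78-0.92]  PPV 0.84  NPV 0.92  F1 0.88
```

Sensitivity is tp/(tp+fn) = 84/92: of the 92 exams the reference review calls
true outliers, the detector flagged 91%. The bracketed intervals are
two-sigma normal-approximation 95% CIs.

The full pipeline on a synthetic cohort:

```r
report <- run_pipeline(list(seed = 42, synthetic = list(n_exams = 20000)))
report
#> ct_run_report (seed 42)
#>   exams: 20000 in, 17631 retained; columns: 31 encoded, 7 kept, 7 selected
#>   top numeric predictors: tube_current > kvp > weight > collimator_width > reference_mas
#>   rr     flagged 0.87% overall (0.99% test), R^2 = 0.757
#>   ols    flagged 1.28% overall (1.47% test), R^2 = 0.771
#>   cutoff flagged 1.02% overall (1.25% test)
#>   validation vs injected truth (2 dp):
#>  method sensitivity_2dp specificity_2dp ppv_2dp npv_2dp f1_2dp
#>      rr            0.79            1.00    0.89       1   0.84
#>     ols            0.70            0.99    0.54       1   0.61
#>  cutoff            0.53            1.00    0.52       1   0.53
```

Reading the report: ~12% of records fall to the filters (head exams, missing
dose/weight); of 31 encoded columns, 7 survive the correlation prune (the five
dose-driving numerics plus two protocol indicators — decoys such as age and
pitch factor are removed); the LASSO ranking recovers the generating effect
order; the robust detector flags about 1% of exams and beats both alternatives
in sensitivity against the injected truth without losing specificity.

A thin CLI wraps the same functions (see `inst/cli/ctoutliers`):

```sh
Rscript inst/cli/ctoutliers run-all --seed 42 --out runs/demo
Rscript inst/cli/ctoutliers validate --counts counts.csv --out runs/val
```

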
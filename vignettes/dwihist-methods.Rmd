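---
title: "Methods: multi-model DWI histogram analysis and Ki-67 prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-model DWI histogram analysis and Ki-67 prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwihist)
```

## The problem

Hepatocellular carcinomas with a high Ki-67 proliferation index (> 20%
positively stained cells) behave more aggressively than those with low
expression, and a non-invasive preoperative read-out of that class is
clinically valuable. Multi-b-value diffusion-weighted MRI offers several
quantitative windows on tumor microstructure: the monoexponential apparent
diffusion coefficient (ADC), the biexponential intravoxel-incoherent-motion
(IVIM) decomposition into tissue diffusion D, pseudo-diffusion D* and
perfusion fraction f, and the stretched-exponential model's distributed
diffusion coefficient DDC and heterogeneity index alpha. `dwihist`
implements the whole analysis chain — voxelwise model fitting over a
whole-tumor ROI, histogram summarization of each parameter map, two-reader
averaging, and a diagnostic logistic model for the Ki-67 class — together
with a digital phantom that makes every stage testable without patient
data.

## Signal models

For b-values b (s/mm²) and baseline signal `s0`:

* monoexponential: `S(b) = s0 exp(-b * ADC)`
* biexponential (IVIM): `S(b) = s0 [(1 - f) exp(-b D) + f exp(-b D*)]`
* stretched exponential: `S(b) = s0 exp(-(b * DDC)^alpha)`

All diffusion coefficients are carried in the display unit 10⁻³ mm²/s
throughout the package (the unit in which liver DWI results are reported);
the decay exponent is formed as `b * coefficient * 1e-3`. A single unit
convention end to end removes the classic 10³ slip between fitting and
reporting. The stretched-exponential form places the power alpha inside
the exponential on the product `b * DDC`, the standard parameterization in
which alpha = 1 reduces exactly to the monoexponential model; a
typographically ambiguous variant that applies the power outside the
bracket is equivalent only after re-parameterization and is not used.

The acquisition emulated by default is a nine-point scheme
(b = 0, 10, 20, 40, 80, 200, 400, 600, 1000 s/mm²); `bvalue_scheme()`
enforces a leading b = 0, strict ordering, and at least four points so the
nonlinear fitters keep positive degrees of freedom.

## Voxelwise fitting

`fit_mono()` is an unweighted log-linear least-squares fit of `log S` on b
over all b-values — exact on noiseless monoexponential data, and the
simplest defensible estimator when every b-value is used.

`fit_biexp()` uses the field-standard segmented strategy, because the
free four-parameter IVIM fit is notoriously unstable in D*: (1) a
log-linear fit over b ≥ 200 s/mm² (the natural split in this scheme, above
which pseudo-diffusion has essentially decayed) yields D and an
extrapolated intercept, whence f = 1 − S_int/S(0); (2) a bounded
one-dimensional search fits D* on the full curve with the other three
parameters held. A bounded Levenberg–Marquardt pass over all four
parameters, initialized from the segmented solution, then polishes the
estimate (`fit_config(refine = )`, default on). The polish matters: with
the segmented fit alone, the residual perfusion signal
`f exp(-200 D*)` still present at b = 200 biases D by up to about 1% when
D* is slow; the joint refinement removes that bias while keeping the
segmented solution as a deterministic, well-conditioned starting point.

D* is constrained to [3, 200] × 10⁻³ mm²/s and estimates on a bound are
returned exactly at the bound. That box is deliberate: whole-tumor D*
percentile statistics then show the characteristic degenerate values
(5th percentile pinned at 3, 95th at 200) that arise when low-perfusion
voxels carry no information about D*. f is clamped to [0, 1].

`fit_stretched()` runs bounded Levenberg–Marquardt over (s0, DDC, alpha)
with alpha in (0, 1], initialized from the mono fit (alpha₀ = 0.9,
DDC₀ = ADC). Monoexponential input lands exactly on the alpha = 1
boundary. A DDC estimate stuck at its lower bound marks the voxel
degenerate (e.g. constant signal).

Optimizer controls default to a cost tolerance of 1e-10 and 200
iterations. Voxels with non-positive or non-finite signal, or with a
non-positive fitted ADC, are excluded from the histogram support rather
than imputed — mirroring how ROIs are curated to discard artifacts;
`fit_roi()` warns when more than 20% of an ROI is unfittable and errors
when all of it is.

## Histogram features

`extract_features()` pools all ROI voxels (whole-tumor volume, not
per-slice) and reports mean; 5th, 50th and 95th percentiles by linear
interpolation of order statistics at rank `1 + (n − 1)q` (the common
default in scientific software, configurable in principle but fixed here
for reproducibility); population (biased) skewness; and population
non-excess kurtosis, for which a normal distribution gives 3 and 1 is the
attainable lower bound. The non-excess convention is the one consistent
with liver-DWI histogram reports in which alpha kurtosis sits near 2.3
and DDC kurtosis near 3.5. Percentiles need support: below 50 valid
voxels the function warns, below 10 it errors.

Two readers are emulated by perturbing the ROI (`simulate_second_reader()`,
seeded random erosion/dilation of the 6-neighbourhood boundary; the
default flip probability 0.1 keeps the Dice overlap with the original
above 0.85 for tumor-sized ROIs). Features — not maps — are averaged
across readers (`average_readers()`), and inter-reader agreement is
quantified by ICC(2,1), the two-way random-effects absolute-agreement
single-measure coefficient, the standard choice for two raters measuring
the same quantity.

## The digital phantom

The phantom generates two Ki-67 classes whose parameter distributions
reproduce the class-wise training summaries of the study cohort
(`hcc_high_ki67_spec()` / `hcc_low_ki67_spec()`; e.g. DDC 0.96 vs 1.15,
f 0.13 vs 0.20, alpha 0.65 vs 0.62) and whose AFP covariate follows the
class-conditional positive rates 24/46 and 6/34.

Distribution families: log-normal for the positive coefficients (ADC, D,
D*, DDC), parameterized so the arithmetic mean equals the target
location, and logit-normal for the bounded f and alpha — physical ranges
hold by construction, without truncation artifacts. Where a class summary
is quoted as median ± IQR (the rows compared by rank-sum tests), the IQR
is converted to a normal-equivalent SD (÷ 1.349) before use. The printed
spreads are inter-subject summaries, so `generate_cohort()` re-centres
the class spec per subject (class spread = inter-subject scale) and draws
voxels around the subject location with an intra-tumor coefficient of
variation (`voxel_cv`, default 0.2); intra-tumor variance is not reported
in the source, so this knob is the minimal additional structure and its
default is a typical whole-tumor heterogeneity level.

Noise is Rician — the magnitude of a complex signal with i.i.d. Gaussian
channels — because magnitude MRI is Rician and the distinction matters
exactly where these models are most sensitive, at low-signal high-b
voxels. The default sigma of 2 on a baseline of 100 (2%) corresponds to a
baseline SNR of 50, a realistic respiratory-triggered liver DWI level.
The default generating model is the biexponential (the richest of the
three), so monoexponential and stretched-exponential fits act as
model-mismatch consumers, as in reality; a pure stretched mode exists for
SEM recovery tests. Tumors are ellipsoids of 50+ voxels on a small grid —
adequate support for percentile statistics, with no attempt at anatomical
realism (no partial volume, motion, or multi-lesion subjects).

`generate_feature_cohort()` additionally samples subject-level feature
vectors directly from the class-wise feature summaries, skipping image
rendering and fitting; this is the right granularity for exercising the
statistical pipeline at realistic cohort sizes. Features of one map share
a latent subject factor with loading `rho`; marginals are unconstrained
by `rho`, and its default 0.97 was calibrated so the feature set's joint
discriminative performance (combined-model training AUC ≈ 0.85–0.9)
matches the reported combined-model performance rather than saturating —
with the side effect, noted as a limitation, that within-map variance
inflation factors exceed the range reported in the source study. An
`afp_exact` mode fixes the AFP-positive counts at the class margins
instead of Bernoulli sampling, for experiments that condition on the
observed AFP table.

What passing phantom-based tests does **not** show: performance on real
liver DWI, where motion, perfusion pulsatility, fat suppression failures
and reader behaviour are all richer than the generator; the phantom
validates the estimators and the statistical machinery, not the clinical
claim.

## Train/test split

`split_train_test()` stratifies by Ki-67 class: the total test size is
`round((1 − ratio) n)` and is apportioned to classes by largest-remainder
rounding, so each class keeps its share within one subject and small
cohorts split stably. An 8:2 split of a 58/44 cohort therefore yields
81/21 — the printed 80/22 of the source cohort is not reproducible by any
deterministic stratified rounding and is treated as a historical
idiosyncrasy of that randomization.

## Diagnostic modelling

`ki67_model()` runs the statistical chain on a per-subject feature table:

1. **Univariate screening** at p < 0.05 — Shapiro–Wilk (0.05) in each
   group decides between the pooled-variance t-test and the Mann–Whitney
   rank-sum test for continuous features (summaries follow the matching
   mean ± SD / median ± IQR convention); 2×2 covariates use the
   chi-squared test without continuity correction when all expected
   counts are ≥ 5 (the correction is toggleable; the uncorrected default
   is documented, not claimed canonical), else Fisher's exact test.
2. **Collinearity** — VIF_j = 1/(1 − R²_j); VIF > 5 flags collinearity.
   The default only reports the flags, matching the practice of treating
   VIF as a diagnostic; a `drop` mode iteratively removes the worst
   offender.
3. **Forward logistic selection** — likelihood-ratio entry at 0.05 (the
   most common reading of a "forward" procedure in clinical software),
   deterministic, ties broken by candidate order. A candidate that
   perfectly separates the outcome on its own raises an error naming it;
   a candidate whose addition merely destabilizes the MLE mid-selection
   is skipped. Separation is judged on per-SD-scaled coefficients so
   small-unit predictors are not misflagged.
4. **Assessment** — empirical ROC with AUC by the rank statistic, optimal
   cutoff maximizing Youden's J with ties broken toward higher
   specificity, DeLong confidence interval (via pROC); Hosmer–Lemeshow
   with deciles of risk and G − 2 degrees of freedom; an equal-width-bin
   calibration curve with its mean absolute error; and decision-curve
   analysis, `NB(pt) = TP/n − FP/n · pt/(1 − pt)`, against treat-all and
   treat-none.

The fitted object carries the standard modelling surface: `print()`,
`summary()`, `coef()`, `predict(newdata)`, `residuals()`, `plot()` (ROC,
calibration or decision curve) and `evaluate_ki67_model()` for held-out
data.

## Numerical choices and edge cases

* Estimates on a box bound are snapped exactly to the bound (within 1e-6
  relative) so degenerate-percentile fingerprints are bit-reproducible.
* `roc_analysis()` auto-orients scores so AUC ≥ 0.5 and reports the
  orientation; constant scores return AUC 0.5 with a warning and no
  cutoff.
* Hosmer–Lemeshow grouping collapses tied probability quantiles with a
  warning; fewer than three groups yields no p-value rather than a bogus
  one.
* Calibration bins with no observations are dropped with a warning.
* All randomness flows through explicit integer seeds; cohorts, splits,
  jittered masks and pipeline runs are bit-reproducible given the seed,
  and `run_pipeline()` records seed, configuration and output checksums
  in a JSON manifest.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run at sizes chosen to make Monte-Carlo conclusions
stable while staying comfortably interactive: 1,000 noise-free truth
draws per model for recovery (300 in the acceptance script), 50 curves
per nonlinear model against a multi-resolution grid-search oracle refined
to 0.1% spacing, 500 replicates of n = 1,000 for the Hosmer–Lemeshow
size check, 10⁵ samples for the normal skewness/kurtosis limits, and 25–50
seeded cohort replicates (46 high / 34 low) for the diagnostic-pipeline
quantities.

## Known limitations

* The recovery-rate experiment for the combined-model structure shows
  that, at the class separations implied by the published summary tables
  and n = 80, the third predictor's conditional likelihood-ratio test has
  only ~0.90–0.95 power per component; the joint "DDC feature + AFP both
  selected" rate is ~0.85, so exact replication of the published
  three-predictor model should not be expected in every resample of such
  a cohort.
* The feature-level generator reproduces class-wise marginals and a
  plausible joint correlation, not the full (unpublished) joint
  distribution of real histogram features.
* D* is reported but, as in the source cohort, carries little
  class-discriminative information and is fragile at low f; its bounds
  dominate its percentile features.
* The image-level pipeline fits every ROI voxel independently; no spatial
  regularization is attempted (out of scope by design).
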
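# dwihist

Whole-tumor histogram analysis of multi-model diffusion-weighted MRI
(DWI), and a diagnostic pipeline for dichotomized Ki-67 expression in
hepatocellular carcinoma (HCC).

Ki-67 is a proliferation marker: HCCs with more than 20% Ki-67-positive
cells recur earlier and behave more aggressively, but the index is only
available after surgery. Multi-b-value DWI offers a non-invasive
surrogate. `dwihist` implements the full analysis chain a reader of such
studies needs to reproduce or stress-test:

* **Signal models** — for b-values b (s/mm²) and baseline `s0`:
  monoexponential `S(b) = s0·exp(−b·ADC)`; biexponential (IVIM)
  `S(b) = s0·[(1−f)·exp(−b·D) + f·exp(−b·D*)]`; stretched-exponential
  `S(b) = s0·exp(−(b·DDC)^α)`, α ∈ (0, 1]. Coefficients are carried in
  10⁻³ mm²/s throughout.
* **Voxelwise fitting** (`fit_mono`, `fit_biexp`, `fit_stretched`,
  `fit_roi`) — log-linear ADC; segmented IVIM (split at b = 200 s/mm²)
  with a bounded Levenberg–Marquardt polish and D* clamped to
  [3, 200]×10⁻³ mm²/s; bounded stretched-exponential fit.
* **Histogram features** (`extract_features`, `roi_histogram_features`)
  — mean, 5th/50th/95th percentiles, skewness, non-excess kurtosis of
  each parameter map over the whole-tumor ROI, with two-reader
  simulation, feature averaging and ICC(2,1) agreement.
* **Diagnostic statistics** (`ki67_model`, plus the individual pieces
  `compare_feature`, `compare_categorical`, `vif_screen`,
  `forward_logistic`, `roc_analysis`, `hosmer_lemeshow`,
  `calibration_curve`, `decision_curve`) — normality-gated univariate
  screening, VIF collinearity check, forward likelihood-ratio logistic
  selection, ROC with Youden-optimal cutoff and DeLong CI, calibration
  and decision-curve analysis.
* **Digital phantom** (`generate_cohort`, `generate_feature_cohort`) —
  seeded two-class cohorts with Rician noise whose parameter and feature
  distributions reproduce published class-wise summaries, at image level
  (NIfTI in/out) or directly at feature level.

## Worked example

Fit the IVIM model to a noiseless nine-point decay and recover the
generating parameters exactly:

```r
library(dwihist)
b   <- bvalue_scheme()  # 0, 10, 20, 40, 80, 200, 400, 600, 1000 s/mm^2
sig <- biexp_signal(b, d = 0.83, d_star = 59.48, f = 0.13, s0 = 100)
fit_biexp(sig, b)
#> biexp-model DWI fit (9 b-values)
#>     s0      d d_star      f
#> 100.00   0.83  59.48   0.13
#> residual norm 2.01e-14 | converged: TRUE
```

Generate a synthetic 80-subject cohort (46 high / 34 low Ki-67) carrying
the stretched-exponential and perfusion-fraction features plus the AFP
covariate, and fit the diagnostic model:

```r
cohort <- generate_feature_cohort(seed = 42, maps = c("ddc", "f"),
                                  afp_exact = TRUE)
model  <- ki67_model(cohort)
model
#> Ki-67 diagnostic model (n = 80, prevalence 0.57)
#> screened 9/13 candidates; selected: f_mean, f_p95, afp_high, ddc_p5, ddc_p50
#> training AUC 0.948 (95% CI 0.897-1.000)
```

`summary(model)` adds the screening table (test used and p-value per
candidate), the VIF table, the selected model's odds ratios, the
Hosmer–Lemeshow fit test and the calibration MAE; `predict(model,
newdata)` and `evaluate_ki67_model(model, test_set)` score held-out
subjects; `plot(model, "roc")` draws the ROC curve.

A binary marker's diagnostics follow directly from its 2×2 table. For
the AFP-by-Ki-67 training table (24/46 vs 6/34 positives):

```r
scores <- rep(c(1, 0, 1, 0), times = c(24, 22, 6, 28))
labels <- rep(c(1, 0), times = c(46, 34))
roc_analysis(scores, labels)
#> AUC 0.673 (95% CI 0.575-0.770); cutoff >= 1: sensitivity 52.2%, specificity 82.4%
```

i.e. AUC 0.673 with sensitivity 52.2% and specificity 82.4% at the
Youden-optimal cutoff — for a binary marker the AUC equals
(sensitivity + specificity)/2.

The end-to-end imaging pipeline (phantom → voxelwise fits → two-reader
features → split → model → manifest) is one call,
`run_pipeline(default_run_config())`, and a thin CLI wrapper lives at
`inst/cli/dwihist.R` (`simulate | fit | features | analyze | all`, each
taking `--config`, `--seed`, `--out`).

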
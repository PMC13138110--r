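# lutadose

Dosimetry and dose–response analysis for multi-cycle
[<sup>177</sup>Lu]Lu-DOTATATE radiopharmaceutical therapy of
neuroendocrine tumors.

In this setting each patient receives four treatment cycles; after each
cycle, quantitative SPECT/CT at 4, 24 and 72 h yields a handful of
absorbed-dose-rate samples per tumor and for the kidneys. `lutadose`
turns those sparse samples into the dose metrics that predict radiologic
response, and models the dose–response relationship:

* **Kinetic fitting** — the dose-rate curve of each structure and cycle is
  fitted with the constrained biexponential clearance model
  D'(t) = A·(e<sup>−λ₁t</sup> − e<sup>−λ₂t</sup>), with the washout
  half-time ln2/λ₁ bounded by the 159.5 h physical half-life of
  <sup>177</sup>Lu, and integrated in closed form to the absorbed dose
  AD = A·(1/λ₁ − 1/λ₂).
* **Patient metrics** — lesions with a first-cycle volume ≥ 10 cm³ enter
  unweighted per-cycle means; from these come the cumulative absorbed
  dose cAD = Σ mean-AD per cycle, and the cyclic uptake-decline biomarker
  ΔAD/AA, the percent change of mean AD per administered activity from
  cycle 1 to cycle 4.
* **Activity adaptation** — the trial rule that personalises administered
  activity against a 23 Gy cumulative kidney dose target (7.4 GBq
  standardized first cycle, 11.1 GBq per-cycle cap).
* **Dose–response models** — patients sorted by a dose metric are binned
  into groups of 11; the percent of partial responders per group is
  fitted with the sigmoid P(cAD) = P<sub>max</sub> / (1 +
  e<sup>−(cAD−D<sub>half</sub>)/k</sup>), with R² and RMSE goodness of
  fit; patient-level logistic and RBF-SVM classifiers on
  (cAD, ΔAD/AA) are evaluated by stratified 5-fold cross-validated ROC
  AUC; Wilcoxon and Spearman rank statistics round out the cohort
  analysis.
* **Partial-volume correction** — a synthetic spherical-insert phantom,
  adaptive-threshold segmentation and a saturating recovery-coefficient
  curve RC(V) = 1 − e<sup>−(V/v₀)^b</sup> provide a testable stand-in for
  the imaging front end.
* **Synthetic cohorts** — a calibrated generator (`cohort_config()`,
  `generate_cohort()`) reproduces the statistical structure of such a
  trial (cycle-1 tumor AD/AA median 3.2 Gy/GBq, kidney 0.43 Gy/GBq,
  tumor washout median 79.5 h, ~10% median per-cycle uptake decline,
  response drawn from a sigmoid in true cAD), so the entire pipeline is
  testable without patient data.

## Worked example

Fit a single tumor-cycle curve from its three dose-rate samples:

```r
library(lutadose)
fit <- fit_biexponential(c(4, 24, 72), c(0.81, 1.95, 1.27))
fit
#> Biexponential dose-rate fit
#>   A        : 3.007 Gy/h
#>   washout  : t1/2 = 58.08 h (lambda1 = 0.01193 /h)
#>   uptake   : t1/2 = 7.3 h (lambda2 = 0.09495 /h)
#>   AD       : 220.3 Gy
#>   SSE      : 6.163e-32 (Gy/h)^2 over 3 samples
```

The three samples are exactly interpolated (three parameters, zero SSE):
this cycle delivered 220.3 Gy, clearing with a 58 h washout half-time
after a 7.3 h uptake phase.

Recommend the next administered activity for a patient whose first cycle
(7.4 GBq) showed a kidney AD/AA of 0.43 Gy/GBq:

```r
adapt_activity(0.43, 7.4, n_total_cycles = 4)
#> [1] 11.1
```

The raw recommendation — (23 − 7.4·0.43)/3 Gy per remaining cycle at
0.43 Gy/GBq, i.e. 15.36 GBq — exceeds the per-cycle maximum, so the
11.1 GBq cap binds.

Run the full pipeline on a simulated 73-patient trial:

```r
report <- run_pipeline(cohort_config(n_patients = 73, seed = 1))
#> pipeline: 73 patients summarized, 0 excluded (no lesion >= 10 cm^3), 72/824 fits clamped
report
#> 177Lu-DOTATATE dose-response report (generate mode, seed 1)
#>   73 patients (0 excluded), 824 curve fits (72 clamped)
#>   sigmoid(cAD): Pmax = 99.0%, Dhalf = 152.4 Gy, k = 47.5 Gy (R^2 = 0.93, RMSE = 8.4%)
#>   median successive AD/AA decline: 8.6% per cycle
#>   cross-validated AUC: logistic=0.847 svm=0.814 cad_only=0.863 delta_only=0.438
```

At n = 73 the grouped sigmoid recovers the generating dose–response curve
(plateau 100%, half-dose 135 Gy, steepness 58 Gy) only roughly — seven
group points carry substantial binomial noise — while the median per-cycle
AD/AA decline lands near the generating 10%. `run_pipeline(...,
output_dir = )` writes the cohort, fit table, patient summary, group
table, model JSONs and a run manifest; `inst/cli/lutadose.R` wraps the
same calls for shell use.

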
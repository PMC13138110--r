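---
title: "Models and methods behind lutadose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lutadose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lutadose` implements the dosimetric analysis chain used in multi-cycle
[^177^Lu]Lu-DOTATATE therapy of neuroendocrine tumors: from sparse
absorbed-dose-rate samples per structure and cycle, through patient-level
dose metrics, to dose--response models of radiologic response. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices that were genuinely open.

## The clearance model and its constraint

The absorbed-dose rate of a tumor or kidney after injection is modelled as
a biexponential with a single shared amplitude,

$$\dot D(t) = A\left(e^{-\lambda_1 t} - e^{-\lambda_2 t}\right),$$

where $\lambda_1$ (1/h) is the washout rate, $\lambda_2 > \lambda_1$ the
uptake rate, and $A$ (Gy/h) the amplitude. The curve starts at zero, peaks
at $t^\* = \ln(\lambda_2/\lambda_1)/(\lambda_2-\lambda_1)$, and decays at
$\lambda_1$. The total absorbed dose is the closed-form integral

$$AD = \int_0^\infty \dot D(t)\,dt = A\left(\frac{1}{\lambda_1} -
\frac{1}{\lambda_2}\right).$$

Because effective clearance is the combination of biological washout and
physical decay, apparent retention slower than the ^177^Lu physical
half-life of 159.5 h is physically impossible and can arise only from
measurement error. The fit therefore constrains
$\lambda_1 \ge \ln 2 / 159.5\,\mathrm{h}^{-1}$.

### Fitting three-point data

With samples at 4, 24 and 72 h the model is exactly identified (three
parameters, three observations), so the least-squares fit is usually an
exact interpolation. Numerically, the amplitude enters the model linearly
and is profiled out; the two rates are optimised by Levenberg--Marquardt
(`minpack.lm`) under the reparameterisation
$\lambda_1 = \lambda_{floor} + e^u$, $\lambda_2 = \lambda_1(1 + e^v)$,
which makes both the ordering and the positivity constraints
unconditional. Starting values take the washout rate from the log-linear
slope of the last two samples (falling back to the physical decay constant
when that slope is non-positive, which happens when the curve is still
near its peak at the second sample) and sweep several uptake/washout
ratios.

The constraint is handled literally: the unconstrained optimum is located
first, and only if its washout half-time exceeds 159.5 h is the model
refitted with $\lambda_1$ fixed at the physical decay constant, with the
result flagged `clamped`. Noise-free data that decay slower than physical
decay always clamp. Under measurement noise a small minority of three-point
draws are exactly interpolated by a curve with a *feasible* washout even
when the generating curve was slower than physical decay; such fits
legitimately do not clamp (a dense grid scan confirms no competing
infeasible optimum), which is why the package asserts universal clamping
only for noise-free input.

### Estimator properties worth knowing

Three-point fitting at 10% multiplicative noise is a hard regime. Two
systematic effects, quantified by the package's own simulations, should be
kept in mind when interpreting cohort medians:

* the fitted absorbed dose has a right-skewed error (its *mean* across
  fits sits several percent above truth while its median is slightly
  below), so patient-level means over several lesions inherit a small
  upward pull, on the order of +2--3% at the default noise level;
* the fitted washout half-time median sits 2--3% below truth, and mixing
  over a heterogeneous cohort amplifies that mildly.

These are properties of the estimator under the stated sampling scheme,
not bugs; the round-trip tests budget for them inside their 5% bands.

## Patient-level dose metrics

Lesions enter the analysis only if their first-cycle volume is at least
10 cm^3^ (boundary inclusive); small structures carry too much
partial-volume uncertainty. Patient-level per-cycle metrics are
*unweighted* arithmetic means across eligible lesions — volume weighting
is a defensible alternative, but the unweighted mean matches the
convention of assigning a patient a single response label regardless of
tumor burden, and is what the package implements throughout.

From the per-cycle means follow:

* **cAD** (Gy): the cumulative absorbed dose, the sum over cycles of the
  per-cycle mean AD;
* **ΔAD/AA** (%): the percent change in mean AD/AA from cycle 1 to the
  final cycle — the cyclic uptake-decline biomarker; negative values mean
  declining uptake efficiency;
* per-cycle percent changes, both against cycle 1 and against the
  previous cycle.

Cycle indices are 1-based everywhere.

### The activity-adaptation rule

The trial's kidney-protection rule is implemented exactly: the first cycle
is standardized to 7.4 GBq; after each cycle the kidney dose delivered so
far is computed from measured kidney AD/AA values, the activity needed to
deliver the remainder of the 23 Gy kidney target is split equally over the
remaining cycles using the *most recent* cycle's kidney AD/AA, and the
recommendation is capped at 11.1 GBq per cycle. With constant kidney AD/AA
and no cap, the projected kidney dose after the final cycle equals the
target exactly — a conservation property the tests assert at 1e-9. At the
cohort-median kidney AD/AA of 0.43 Gy/GBq the raw cycle-2 recommendation
is 15.36 GBq, so the cap binds. Kidneys are treated as one combined
structure; activity reductions for adverse events are exogenous to the
rule.

## Dose--response models

For the grouped analysis, patients are sorted in ascending order of the
dose metric (stable sort) and assigned consecutively to groups of 11, the
final group holding the remainder; a 73-patient cohort yields six full
groups plus one of seven. Each group contributes its median metric and its
percent of partial responders. The response curve

$$P_{PR}(cAD) = \frac{P_{max}}{1 + e^{-(cAD - D_{half})/k}}$$

is fitted to the group points by unweighted least squares with
$P_{max} \in [0, 100]$ (profiled out, as it enters linearly) and $k > 0$.
The remainder group is weighted equally — the goodness-of-fit definitions
are unweighted, so the fit is too. Goodness-of-fit uses
$R^2 = 1 - SSE/SST$ and $RMSE = \sqrt{SSE/n}$ on the percent scale; when
the observed proportions have zero variance $R^2$ is undefined and
flagged rather than forced.

Patient-level classifiers on (cAD, ΔAD/AA) are evaluated by stratified
(class-balanced) 5-fold cross-validation with a recorded fold seed,
pooling out-of-fold scores and computing AUC by the rank (Mann--Whitney)
formulation with mid-rank tie handling; per-fold AUCs are reported
alongside. Three scoring rules are built in:

* the two-feature unpenalised logistic model (via `stats::glm`), with
  complete separation detected (zero residual deviance or extreme linear
  predictors) and flagged instead of silently reporting diverged
  coefficients;
* an RBF-kernel SVM (via `e1071::svm`, features standardized internally,
  cost 1 and kernel width $1/p$ on the standardized scale by default —
  the hyperparameters are deliberately plain because AUC is invariant to
  monotone score calibration), with the decision-score sign fixed
  empirically so that larger always means more responder-like;
* the single features themselves as reference scores (ΔAD/AA negated, as
  decline is the responder-like direction).

Scoring patients by the fitted sigmoid evaluated at their own cAD is a
strictly monotone transform of cAD, so its AUC equals the AUC of cAD
alone — asserted exactly in the tests. Rank statistics (Wilcoxon
signed-rank and rank-sum, Spearman correlation) wrap the standard `stats`
implementations, with the all-zero-differences paired case flagged as
undefined rather than erroring mid-pipeline.

## The synthetic cohort generator

No public individual-level data exist for this setting, so the package
ships a generator whose *defaults are the study conditions*: every
downstream stage is exercised on cohorts whose statistical structure
matches what the analysis assumes.

Per patient: a lesion count on 1--6 with mean 1.9; a cycle-1 tumor AD/AA
drawn lognormal with median 3.2 Gy/GBq (log-sd 0.6, giving a realistically
heavy-tailed uptake distribution); independent per-cycle multiplicative
decline factors with median 0.90 (log-sd 0.10) — independent because the
study found no difference between the magnitudes of successive declines,
and multiplicative so the ~10%-per-cycle summary is scale-free; a kidney
AD/AA lognormal with median 0.43 Gy/GBq, constant across cycles in truth
(the kidney shows no cyclic change); washout half-times lognormal with
medians 79.5 h (tumor) and 47.2 h (kidney); a fixed uptake half-time of
6 h, placing the 4-h sample on the rising edge so the 24/72-h samples
carry the washout information. Lesion-level AD/AA multiplies the patient
trajectory by a mean-one lognormal perturbation (CV 20%) — mean-one so the
patient mean is centred on the patient-level value the calibration targets
refer to. Lesion volumes are lognormal (median 28.4 cm^3^, log-sd 1.0)
truncated to 10--2340 cm^3^ by resampling. Measurement noise on each
dose-rate sample is multiplicative lognormal with CV 10%, mean one —
multiplicative because SPECT quantification error scales with signal.

Two calibration notes. First, the washout log-sd is 0.15, not the ~0.27
one gets by converting the printed standard error of the cohort median
straight into a between-patient SD: that observed spread is of *measured*
half-times, which at three-point sampling carry ~30% estimation CV, and
using it as the truth-level spread would double-count the noise (and
noticeably depress the fitted washout median through the skew effect
described above). The deconvolved, truth-level value is the one consistent
with the generative model. Second, the administered-activity schedule
defaults to the adaptive rule itself (projected from the true kidney
AD/AA), so generated cohorts have realistic cycle-2+ activities near the
11.1 GBq cap and cumulative activities near 41 GBq.

Response labels are drawn Bernoulli from a configurable response model
evaluated at the patient's *true* cumulative dose and true ΔAD/AA — by
default the sigmoid-in-cAD curve at the plateau 100%, half-dose 135 Gy and
steepness 58 Gy, which on default cohorts yields responder fractions near
40%. Non-responders split into stable and progressive disease at a fixed
33:12 ratio independent of dose; no dose-dependent SD/PD mechanism is
modelled because none is identified.

What the generator does *not* emulate: lesion-level response, intra-tumor
dose heterogeneity, activity reductions for adverse events, correlations
between lesion volume and uptake, inter-scanner calibration differences,
or any survival endpoint. Passing round-trip tests on this cohort
therefore demonstrates the pipeline's internal consistency under the
stated noise model, not the clinical accuracy of SPECT dosimetry.

## The phantom front end

Recovery-coefficient partial-volume correction is exercised on a synthetic
3D phantom: uniform background plus spherical inserts, the sphere excess
convolved with a normalized Gaussian PSF (so total excess signal is
conserved to well under 1%), and optional multiplicative noise. Voxels are
isotropic; volumes are voxel count times voxel volume, with no partial
voxels; world coordinates sit at voxel centers.

Segmentation uses a fixed-point fractional threshold inside an oversized
seed box: $T_{i+1} = f\,\overline{m}_i + (1-f)\,b$, with $\overline{m}_i$
the current mask mean, $b$ a background estimate (median outside the box
by default) and an iteration cap of 100 (flagged if hit; in practice the
mask sequence settles within a handful of iterations). The fraction
defaults to $f = 0.5$: for a sharp-edged object blurred by a symmetric
PSF, the background-corrected half-level contour crosses at the true
boundary, and empirically this recovers blurred-sphere volumes within
~7% at FWHM equal to half the radius, where lower fractions over-grow the
mask substantially. $f$ is exposed for sensitivity analyses.

The recovery curve is the two-parameter saturating form
$RC(V) = 1 - e^{-(V/v_0)^b}$ — strictly increasing, bounded by one, and
approaching one for objects much larger than the resolution — calibrated
from (volume, measured/true) pairs measured in the *known* sphere
geometry, as in physical phantom calibration. Correction divides a
structure-mean value by $RC$ of the structure volume; the package corrects
structure means, not voxel values. On noiseless blurred spheres spanning
11--268 cm^3^ the corrected means are within 5% of truth while
uncorrected means are biased low, monotonically worse for smaller
spheres.

## Numerical and reproducibility choices

* All cohort randomness flows from the single integer seed in the
  configuration; the same configuration is bit-reproducible, and the
  cross-validation fold seed is recorded in every report.
* CSV round trips use full double precision (`data.table`), so a written
  and re-read cohort reproduces its analysis to 1e-12.
* Fits that cannot converge raise typed errors carrying diagnostics
  rather than returning silent NAs; degenerate inputs (all-zero paired
  differences, zero observed variance, empty masks, sub-threshold-only
  patients) are flagged or raised explicitly.
* Ties in dose-metric sorting are broken by original patient order
  (stable sort).
* Default problem sizes used by the package's own verification runs:
  2,000 patients for full fit-pipeline round trips (about 19,000 curve
  fits) and 5,000 patients for grouped dose-response parameter recovery —
  large enough that Monte-Carlo error sits well inside the tolerance
  bands, small enough to run routinely on a laptop.

## Known limitations

* The biexponential form with a shared amplitude is assumed exactly; no
  mono-exponential or trapezoid alternatives are offered.
* Three-point sampling makes per-fit washout estimates noisy (~30% CV at
  10% noise); cohort medians are reliable, individual fits less so.
* The adaptive-threshold scheme and the recovery-curve form are
  simplified, testable stand-ins for scanner-specific procedures; absolute
  recovery values should not be transferred to real scanners.
* Patient-level aggregation hides lesion-level heterogeneity by design.
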
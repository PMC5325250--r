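---
title: "hemorisk: models, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemorisk: models, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemorisk)
```

This vignette is the package's own account of the science it implements:
the perfusion and permeability models, every tunable parameter with its
default and the reason for it, what the synthetic-data generator emulates
and what it deliberately does not, and the design choices made where the
method left the design open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The problem

After reperfusion therapy for acute ischemic stroke, some patients bleed
into the infarct (parenchymal hemorrhage, PH). Three pretreatment MRI
markers, measured inside the diffusion lesion, carry the risk signal: low
cerebral blood volume (CBV, severe hypoperfusion), low apparent diffusion
coefficient (ADC, severe cytotoxic injury), and high microvascular
permeability (K2, blood–brain-barrier disruption). The package measures
these voxelwise from dynamic susceptibility contrast (DSC) and diffusion
MRI, summarizes each lesion by extreme percentiles (10th for CBV and ADC,
90th for K2 — the "lowest/highest representation" of each marker, robust to
within-lesion heterogeneity), and classifies patients with a
fixed-coefficient logistic score and a two-threshold classification tree.

## 2. DSC signal model and the leakage (K2) fit

### Forward model

During bolus passage the T2\*-weighted signal obeys
`S(t) = S0 · exp(−TE · ΔR2*(t))`, with ΔR2\* proportional to contrast
concentration. The generator builds each voxel's concentration as

```
c_v(t) = [ cbf_v · (AIF ⊛ R_v)(t) + k2_v · L(t) ] (t − δ_v)
R_v(t) = exp(−t / MTT_v),  MTT_v = mtt0 · cbv_v / cbf_v
L(t)   = −∫₀ᵗ c_ref / ∫ c_ref
```

so the curve integral is proportional to `cbv_v` (since
`∫ AIF⊛R = ∫AIF · MTT`), the leakage term `k2_v · L` makes the tail return
toward baseline faster (the T2\*-dominant extravasation signature), and the
bolus delay `δ_v` shifts perfusion and leakage jointly. Ground-truth K2 is
defined in exactly the units the fit estimates (the coefficient on the
normalized-integral regressor), so recovery tests are self-consistent;
no vendor's absolute K2 calibration is reproduced, only the decision logic
built on it.

### Fit

`fit_leakage()` regresses each voxel's post-baseline curve on the
contralateral reference curve and `L`, per the model above. Two additions
proved necessary for the fit to mean what it claims on ischemic tissue:

* **Arrival alignment.** The two-regressor model is exact only for
  arrival-aligned curves. An ischemic lesion receives the bolus several
  seconds late, and regressing a delayed curve on an undelayed reference
  pushes enormous error into the ramp-shaped leakage regressor (with the
  default 8 s lesion delay the naive fit mis-estimates K2 by more than 1 in
  absolute value — measured during development, reproduced by
  `align = FALSE`). The regressor pair is therefore searched over a delay
  grid (0–12 s, 0.25 s steps, linear interpolation between frames) and the
  smallest-residual shift kept, ties to the smaller delay. The grid step is
  an accuracy/cost dial; 0.25 s is far below the frame interval.
* **Baseline-offset intercept.** Estimating S0 from finitely many noisy
  baseline frames, plus the curvature of the log transform, leaves each
  voxel's concentration curve with a small constant offset. A constant
  couples into the ramp regressor and biases K2 downward (about −7% of the
  median at SNR 50 without the intercept, about −2% with it; the noiseless
  contract examples are unaffected since the fitted offset is then exactly
  zero). The offset `b0` is reported and removed before CBV integration.

Negative K2 (T1-dominant leakage) is retained, not clipped; the 90th
percentile summary is robust to that tail. All time integrals use the
trapezoid rule (simple, second order, standard).

### CBV ratio and Tmax

Voxel CBV is the post-baseline trapezoidal integral of the corrected curve
(`conc − K2·L(t−δ) − b0`), divided by the mean over the contralateral
reference ROI — so the reference region averages exactly 1 by
construction. Negative corrected integrals are kept and counted in QC.
Tmax comes from truncated-SVD deconvolution by the arterial input function
(Toeplitz formulation; singular values below 0.15 of the maximum
discarded — a standard, deterministic substitute for proprietary Bayesian
deconvolution), with Tmax the argmax of the recovered residue, quantized to
the frame interval. With linear-interpolation shifting, a sub-frame delay
splits its mass between neighboring frames, so the argmax tips to the next
frame once the delay approaches half the per-frame residue decay
(~0.36 s at MTT 4 s, Δt 1.5 s); delays are recovered to within one frame.

## 3. Lesion VOI and features

* **Registration**: exhaustive integer-translation search maximizing mutual
  information on a 32-bin joint histogram; ties to the smaller shift, then
  lexicographic; a best score less than 4 SD above the mean over all
  candidate shifts (a peakless surface, as for unrelated images) flags the
  result low-confidence. Full 6-degree-of-freedom registration is out of
  scope; synthetic volumes are generated on a common grid.
* **VOI**: DWI voxels more than `z_thr = 2` SD above the contralateral
  mean, largest 26-connected component, interior holes filled. The
  underlying clinical method ("voxel-based signal intensity") is otherwise
  unspecified; the z-rule is the package's stand-in and both parameters are
  configurable. A perfectly uniform image yields an empty VOI (not an
  error); feature extraction refuses empty VOIs.
* **Percentiles**: linear interpolation between order statistics (R type 7;
  e.g. values 1..100 give p10 = 10.9, p90 = 90.1). The convention is fixed
  so thresholds are convention-stable.
* **Volumes**: infarct core counts voxels with ADC strictly below
  600×10⁻⁶ mm²/s; the perfusion lesion counts Tmax ≥ 6 s inclusive;
  global reperfusion is a ≥90% reduction of that volume (follow-up exactly
  10% of baseline counts as reperfused); the inequalities mirror the
  printed decision rules. A median brain ADC outside 200–2000 triggers a
  unit-mismatch warning.

## 4. Predictive models

The published logistic score is `1.75 − 9.526·CBV10 + 2.7924·K2_90` with
decision threshold −1.45. The CBV coefficient is negative: the sign is
required both for low CBV to raise risk (the direction every marker
analysis shows) and for the worked-example patient (CBV10 0.40, K2_90 0.32,
who went on to hemorrhage) to classify as PH. A score exactly at the
threshold, and a feature exactly at a tree cut, counts as the PH side —
boundary handling is otherwise unspecified and this choice is applied
consistently.

The published tree covers two quadrants (low CBV + high K2 → PH; high CBV +
low K2 → no PH). The two mixed quadrants are resolved by a recorded policy:
default falls back to the logistic score; alternatives use the CBV root
split alone or the cohort-majority class.

Fitting procedures are implemented from scratch:

* **Backward-stepwise logistic regression**: IRLS (convergence
  max|Δβ| < 1e-8, ≤100 iterations) on per-variable standardized predictors
  (conditioning; the separation guard |β| > 30 is then in log-odds-per-SD),
  mapped back to raw scale with the full covariance transform; repeatedly
  drop the largest Wald p > α (= 0.05) and refit. Wald rather than
  likelihood-ratio tests: standard stepdown practice, cheap, deterministic.
  Constant/collinear candidates are dropped with a warning; separation is
  flagged with coefficients at the last stable iterate. The fitted model's
  decision threshold is chosen on the training scores by maximizing
  (sensitivity+specificity)/2, mirroring how the published threshold was
  chosen. The test suite checks the IRLS against `stats::glm` as an
  independent oracle.
* **Recursive partitioning**: exhaustive search over candidate features and
  midpoints of consecutive distinct values, maximizing Gini impurity
  decrease ("groups as different as possible"); ties break to the earlier
  candidate, then the lower threshold; recursion to depth 2 with ≥5
  records per leaf (the published tree's shape); leaf ties predict no-PH.
  Note that a depth-1 tree coincides with the balanced-accuracy-optimal
  single threshold only when the classes are separable — Gini and
  (sens+spec)/2 optimize different functionals under overlap with
  imbalance — so that reduction is asserted on separable data.
* **Metrics**: overall accuracy is defined as (sensitivity+specificity)/2
  throughout; AUC uses the rank (Mann–Whitney) formulation with half-credit
  for ties, oracle-tested against exhaustive pair enumeration; Spearman
  correlations use average ranks.

## 5. The synthetic cohort: what it states, and what a green test means

Defaults reproduce the analysed trial cohort: 83 patients, 20 with PH (24%
prevalence), clinical covariates drawn independently of the label (no
clinical variable predicted PH in the source analysis) with the reported
demographics (age 66 ± 15.2, 45/83 men, NIHSS centred on 17, IV tPA 31/83,
thrombectomy 41/83).

**Group feature distributions.** The source tables' group statistics are
not available as text, so the per-arm generating distributions of
(CBV10, ADC10, K2_90) were derived a priori from the published
single-classifier operating points by inverting the normal quantile at the
stated sensitivity and specificity with field-plausible SDs, and then
frozen. For a threshold `c` with sensitivity `se` in the PH arm (low
predicts PH): `μ_PH = c − qnorm(se)·σ_PH`, and with specificity `sp` in the
no-PH arm `μ_noPH = c + qnorm(sp)·σ_noPH` (mirrored for K2, where high
predicts PH). With (c, se, sp) = (0.45, 0.95, 0.698) for CBV10 at σ = 0.12
/ 0.25, (320, 0.80, 0.587) for ADC10 at σ = 90 / 110, and
(0.28, 0.90, 0.603) for K2_90 at σ = 0.12 / 0.12:

| feature | PH mean | no-PH mean |
|---|---|---|
| CBV10 | 0.2526 | 0.5797 |
| ADC10 (10⁻⁶ mm²/s) | 244.3 | 344.2 |
| K2_90 | 0.4338 | 0.2487 |

**Imaging world.** 64×64×16 voxels of 2×2×5 mm by default (0.02 mL/voxel;
the pipeline's default config uses a smaller grid so an 83-patient run
stays desk-scale — percentiles are taken over hundreds of lesion voxels
either way); ellipsoidal brain, spherical lesion (radius 12–20 mm per
patient) with a mirrored 10 mm contralateral white-matter ROI; within-lesion
voxel SDs 0.15 / 120 / 0.08 for CBV/ADC/K2, means placed so the lesion's
own percentiles hit the drawn per-patient targets; contralateral CBV
recentred to mean exactly 1. Acquisition: TE 45 ms, Δt 1.5 s, 40 frames
(60 s, within the 45–60 s convention), 8 pre-bolus frames, S0 = 100,
gamma-variate AIF (shape 3, scale 1.5 s) arriving 2 s after the baseline
window with a 0.3-amplitude recirculation pass delayed 12 s — parameters
chosen to reproduce the canonical curve morphology (first pass, smaller
recirculation peak, decline toward baseline), all configurable. Reference
peak ΔR2\* is 8 s⁻¹ (≈30% signal drop, moderate dose). Noise is additive
Gaussian on the signal (magnitude-MRI behaviour at moderate SNR keeps the
log transform testable); SNR 50 means σ = S0/50. Lesion bolus delay 8 s
(comfortably beyond the 6 s perfusion-lesion cut), MTT uniform at 4 s: CBF
numerically tracks CBV so each voxel's curve is a scaled, delayed copy of
the reference plus leakage — precisely the regime in which the
two-regressor model is exactly specified. Heterogeneous MTT can be set via
`cbf_map` but then the leakage model is misspecified by construction and
recovery guarantees do not apply.

**Label modes.** Default: labels first (exactly `n_ph` positive), features
per arm. For end-to-end fidelity checks: features from the
prevalence-weighted mixture and the label assigned deterministically by the
published logistic rule on the generating features — so pipeline accuracy
measures feature-measurement fidelity alone, not label noise.

**What a green test does not establish.** No anatomy, bias fields, motion,
partial-volume structure or DICOM semantics; percentile features computed
from noisy maps are biased outward relative to the generating targets (at
SNR 50 the per-voxel K2 noise SD is ≈0.2, so a lesion's *90th percentile*
K2 is inflated even though the *median* is nearly unbiased — which is why
the K2 recovery criterion pools lesion medians over replicate patients, and
why the end-to-end criterion uses the decision-rule labels rather than
percentile equality); group separations and model accuracies on this cohort
say nothing about a clinical population beyond the stated structure.

## 6. Numerical conventions and degenerate inputs

Voxels with any non-positive signal (or non-positive S0) are flagged and
excluded from all fits rather than raising; an empty mask or an all-flagged
reference ROI is an error. A reference curve proportional to its own
integral (only possible for a non-peaked "bolus", e.g. an exponential)
makes the leakage design singular and is an error at zero shift. The
registration scores shifts with empty overlap as invalid. Cohort tables use
a fixed, documented column order (`cohort_columns()`); CSV is
comma-separated UTF-8 with a header and '.' decimals; every report is JSON
with full-precision floats (round-trip < 1e-12); each run directory
carries a MANIFEST recording stage completion and the seed. Per-patient
simulation seeds are derived from the master seed and kept below 2³¹.

## 7. Known limitations

* The two-regressor K2 is a relative, convention-bound quantity; absolute
  thresholds (0.28) transfer only within the same normalization.
* Arrival alignment estimates delay per voxel by residual minimization; at
  very low SNR the delay posterior is flat and K2 variance grows
  accordingly.
* Backward elimination retains each null covariate with probability ≈ α by
  construction, so "exact support recovery" against many null candidates is
  bounded near `(1−α)^k` no matter the implementation; support-recovery
  guarantees are therefore stated for the generating candidates, and
  retention of the true pair for the full candidate set.
* The published tree's mixed quadrants are genuinely undefined by its two
  printed rules; every prediction records the policy used.
* ROC areas of the source cohort depend on unavailable clinical data and
  are not reproduced; the acceptance suite substitutes property-based
  checks (oracle agreement, parameter recovery, end-to-end accuracy bounds).
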
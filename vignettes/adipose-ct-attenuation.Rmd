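---
title: "Measuring peritumoral breast adipose tissue attenuation and its prognostic value: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring peritumoral breast adipose tissue attenuation and its prognostic value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoct)
```

## The scientific question

Adipocytes in direct contact with breast cancer cells lose lipid content and
shrink ("cancer-associated adipocytes"), and denser fat attenuates X-rays
less negatively. On non-contrast CT this shows up as an *elevated* (less
negative) Hounsfield-unit value of the fat immediately around the tumor
relative to fat far from it. `adipoct` implements the measurement of this
effect from paired PET/CT volumes and the survival analysis that asks whether
it predicts recurrence after surgery:

* **TAT HU** — mean attenuation of tumor-adjacent breast adipose tissue,
  sampled in a spheroid VOI that covers the lesion plus a 1-cm shell;
* **CAT HU** — the same measurement in a mirrored VOI over the contralateral
  breast;
* **HU difference** = TAT − CAT, and
  **HU difference %** = (CAT − TAT)/CAT × 100. Because fat attenuation is
  negative, both carry the same sign: positive when peritumoral fat is denser.

Since no patient images are distributed, every step runs on synthetic data
with known ground truth: a geometric PET/CT phantom and a cohort simulator.
That choice defines what the test results mean — see *Limitations*.

## The phantom

`phantom_spec()` describes two mirror-symmetric fat ellipsoids (breasts)
about the sagittal midplane, each with a concentric fibroglandular core, and
a spherical tumor in one breast. Defaults: a 160×100×16 grid at 1×1×5 mm
(the 5-mm CT slice thickness of a PET/CT attenuation scan), fat at
−100 ± 4 HU, gland at +40 HU, tumor at +30 HU, tumor radius 10 mm, tumor
uptake 8.44 SUV over a 0.5 SUV background, and additive Gaussian acquisition
noise (3 HU, 0.05 SUV). Fat within `peritumoral_reach_mm` of the tumor
surface is shifted by `peritumoral_delta_hu` (default +9 HU, matching the
median published difference of ~8.7 HU).

Two deliberate simplifications:

* the peritumoral elevation is a **uniform additive shift** with a hard
  reach, not a decaying gradient — the simplest model consistent with a
  measurement that averages over a 1-cm shell;
* noise is additive Gaussian; CT streak/quantum artifacts and PET
  reconstruction texture are not modeled.

**Why the reach defaults to 12 mm, not 10.** The tumor VOI is built as the
minimal enclosing spheroid of the mask dilated by the 10-mm margin. On a
discrete, anisotropic grid that spheroid can bulge slightly past 10 mm from
the tumor surface. With a 12-mm reach, every fat voxel inside the VOI is
shifted, so a noiseless phantom reproduces the programmed TAT and CAT means
*exactly* — which is the invariant the phantom exists to provide. A 10-mm
reach would leave a thin rind of unshifted fat inside the VOI and bias TAT
by a grid-dependent fraction of a HU.

## VOI construction

The published measurement drew spheroid VOIs by hand; a reproducible rule is
needed instead. `tumor_voi()`:

1. dilate the tumor mask by a Euclidean ball of radius `margin_mm`
   (default 10 mm) in world millimetres;
2. center the VOI at the dilated bounding-box center, initialize semi-axes
   at the half-extents (floored at half a voxel);
3. inflate all semi-axes by the smallest common factor `s ≥ 1` such that
   every dilated voxel center satisfies the ellipsoid inequality.

This is deterministic and containment-exact: the VOI provably contains 100%
of the dilated tumor voxels (tested by brute-force enumeration). For a
spherical mask it reduces to the dilated sphere (`s = 1`); for a cubic mask
`s` approaches √3, the worst case. `mirror_voi()` reflects the center's
left-right coordinate about the sagittal midline and keeps the size — on an
aligned grid this is exactly "same size, same quadrant, contralateral side".
The midline comes from phantom metadata (or configuration for user data);
no registration is attempted.

Voxel membership is by **voxel center**, matching the default of clinical
ROI tools; no partial-volume weighting. The fat window −200…−50 HU is
**inclusive at both ends** (the prose definition of the range is ambiguous;
inclusivity is asserted at the boundary in the tests). A side with fewer than
`min_voxels = 10` fat voxels raises a dedicated condition, operationalizing
the study's "insufficient breast adipose tissue" exclusion.

PET readouts within the tumor VOI: `suv_max()` is the voxel maximum;
`metabolic_tumor_volume()` counts voxels with SUV ≥ 2.50 (threshold
inclusive) times the voxel volume, so a lesion whose SUVmax is below the
threshold has MTV exactly 0.0 cm³. SUV conversion (`to_suv()`) uses the
body-weight convention — the most common clinical default; lean-body-mass
SUV is not implemented.

## The cohort simulator

`cohort_spec()`/`simulate_cohort()` generate the statistical substrate for
the survival analysis. Defaults reproduce the published marginals: 287
patients; T1/T2/T3 at 47.4/44.6/8.0%; nodal involvement drawn conditional on
T stage (20/42/70%) to give ~34% node-positive; ER+ 74.2% with PR drawn
conditional on ER (78% vs 15%), which yields ~11% triple-negative disease —
close to the published 11.5%, which independent marginals would not give;
HER2+ 49.5%; Ki67+ 61.7%; grades 23.4/49.7/26.9%.

CAT HU is Normal(−97.54, 7) with slope −0.58 HU per BMI unit (Spearman rank
correlation ≈ −0.27 with BMI, the published direction and size). The
TAT−CAT shift is Normal with location
`6.0 + 3.0·T2 + 5.0·T3 + 1.8·ER− + 1.8·PR− + 1.5·grade3` and SD 5 HU. The
published record gives group means and SDs but **no joint distribution**, so
these magnitudes are a stated assumption calibrated to reproduce the
qualitative structure (higher shift with stage, receptor negativity and
grade), not a reconstruction.

Recurrence times are exponential with hazard
`h0 · exp(Σ β_j (x_j − x̄_j))` over the numeric columns named in
`hazard_coef`. The default is a single coefficient, `ln(1.10)` per HU of TAT
HU — the published univariate hazard ratio. Using *all* published univariate
ratios jointly would be wrong: univariate estimates absorb each other's
confounding, so programming them simultaneously would not reproduce any of
them. `h0` is calibrated deterministically per cohort (closed-form expected
event fraction for exponential times under uniform censoring, solved by
`uniroot`) so that the expected observed-event fraction is 10.5% under
administrative censoring uniform on 6.1–88.9 months.

`simulate_reader_pair()` adds independent Gaussian reader noise twice to a
truth vector; under this model the population concordance is
`var(truth) / (var(truth) + reader_sd²)`, which is how the default reader SD
(1.6 HU, concordance ≈ 0.95 at a 7-HU truth SD) was derived.

All generators consume one explicit seed per call and restore the caller's
RNG state; identical (spec, seed) give bit-identical output.

## The statistical battery

Standard machinery is delegated: Cox regression (Efron ties), Kaplan–Meier
and log-rank to `survival`; t, Kruskal–Wallis, Spearman and Fisher's exact
test to base `stats`. Written here because no installed package provides
them, and verified against independent oracles in the tests:

* **Lin's concordance correlation** with population moments and a Fisher-z
  interval using Lin's 1989 variance (the original report does not state its
  CI method; this is the conventional choice).
* **Conover–Iman post-hoc** after a significant Kruskal–Wallis test —
  rank-based t statistics with the pooled rank variance, the procedure of
  the MedCalc software family. Run only when the omnibus p < 0.05; no
  multiple-testing correction anywhere, mirroring the original reporting.
* **Youden-optimal ROC cutoff**: candidate thresholds at midpoints between
  consecutive distinct scores, maximize J = sensitivity + specificity − 1,
  ties broken toward higher sensitivity (the lowest tied threshold, with
  larger scores indicating events). The original says only "optimal cut-off
  by ROC analysis"; Youden with midpoint candidates is the MedCalc-style
  criterion and is checked against exhaustive enumeration.
* **Stratified recurrence table**: within each T-stage stratum (T1 vs
  T2–T3), events/total above and below the cutoff, percentages rounded
  half-up to one decimal (matching the published table formatting; base
  `round()` is banker's rounding and would differ at .05), and a two-sided
  Fisher exact p. Which exact test produced the published p-values is
  unstated; Fisher is implemented and the discrepancy risk documented here
  rather than resolved.

Degenerate inputs are errors, not silent results: zero-variance CCC or
paired differences, constant covariates, single-class ROC labels, and
monotone Cox likelihoods (perfect separation) all raise conditions. The
pipeline's table builders degrade a diverging covariate to an NA row —
with ~30 events, a small simulated cohort can easily have a T-stage level
with no events, which is a property of the data, not a fitting failure.

## The pipeline

`run_study()` expands one root seed into per-stage seeds, generates and
measures phantom cases (truth-vs-measured check), simulates the cohort, and
runs the full battery into a `study_report`; `render_tables()` writes CSV,
markdown and JSON with the config and its MD5 hash embedded. Regenerating
from the same config is byte-identical, which the tests assert. A
user-supplied pre-measured cohort CSV can substitute for simulation by
loading it and calling the table builders directly, since clinical images
cannot ship with the package.

## Problem sizes

Defaults were chosen as the smallest sizes that exercise the geometry
honestly: the default phantom grid is 160×100×16 at 1×1×5 mm (one
measurement ≈ 1 s), the test phantoms 80×60×40 at 1 mm isotropic, cohorts
n = 287 as published, and the parameter-recovery experiment 200 cohorts
(the acceptance script) or 60 (the inspection driver in `analysis/`).

## What passing tests do and do not show

Everything stochastic is checked against *programmed* truth: hazard-ratio
recovery (mean univariate HR within ±0.02 of the programmed 1.10/1.12 over
200 cohorts), event-rate calibration, direction checks (higher recurrence in
high-TAT arms within each stage stratum). These validate the code and the
statistical machinery — they cannot validate the clinical claim. The
cohort-specific published values (cutoff −82.50 HU, concordance 0.953,
adjusted hazard ratios, 5-year RFS rates) depend on undeposited patient data
and are *not* reproducible here; property-based substitutes stand in for
them. Real-data caveats the phantom does not cover: manual VOI placement
variability, partial-volume effects at 5-mm slices, contrast timing, scanner
calibration drift, and non-Gaussian artifact noise.
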
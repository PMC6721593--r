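# adipoct

Peritumoral breast adipose tissue CT attenuation and recurrence-free
survival.

Adipocytes in contact with invasive breast cancer shrink and lose lipid
("cancer-associated adipocytes"), and denser fat shows a less negative
Hounsfield-unit (HU) value on non-contrast CT. `adipoct` measures this
effect on paired PET/CT volumes and evaluates its prognostic value, for
imaging researchers who want the measurement chain and the survival analysis
as tested, reproducible code rather than manual ROI workflows:

* **TAT HU** — mean fat attenuation in a spheroid volume of interest (VOI)
  covering the tumor plus a 1-cm shell (fat window −200…−50 HU);
* **CAT HU** — the same in a size-preserving VOI mirrored across the
  sagittal midline onto the contralateral breast;
* **HU difference** = TAT − CAT and
  **HU difference %** = (CAT − TAT)/CAT × 100;
* **SUVmax** and **MTV** (volume with SUV ≥ 2.50) of the lesion;
* survival analysis: univariate and multivariate Cox proportional hazards
  `h(t | x) = h0(t) · exp(βᵀx)` (Efron ties), Kaplan–Meier curves and
  log-rank tests, Youden-index ROC cutoffs, Lin's concordance correlation
  for inter-reader agreement, Kruskal–Wallis with Conover–Iman post-hoc
  comparisons, and recurrence tables stratified by T stage and dichotomized
  TAT HU with Fisher's exact test.

Because no patient images ship with the package, it includes first-class
synthetic data generators with known ground truth: a two-breast PET/CT
phantom with a programmable peritumoral fat-attenuation shift, and a
287-patient cohort simulator whose recurrence hazard is driven by a
proportional-hazards model (default: hazard ratio 1.10 per 1-HU increase of
TAT HU, event rate calibrated to 10.5% under administrative censoring on
6.1–88.9 months).

## Worked example

```r
library(adipoct)

# a noiseless phantom programmed with a contralateral fat mean of
# -108.743 HU and a +16.28 HU peritumoral shift
spec <- phantom_spec(fat_hu_mean = -108.743, fat_hu_sd = 0,
                     peritumoral_delta_hu = 16.28,
                     noise_sd_hu = 0, noise_sd_suv = 0)
case <- make_breast_phantom(spec, seed = 1)
measure_case(case)
#>    tat_hu   cat_hu hu_difference hu_difference_pct suv_max mtv_cm3
#> 1 -92.463 -108.743         16.28          14.97108    8.44     4.4
#>   n_fat_voxels_tumor_side n_fat_voxels_contralateral
#> 1                    4564                       5300
```

The measurement chain (tumor VOI → mirrored VOI → fat window → means)
recovers the programmed values exactly: tumor-adjacent fat at −92.463 HU,
contralateral at −108.743 HU, so the peritumoral fat reads 16.28 HU denser
(+14.97%). The lesion's SUVmax is the programmed 8.44 and its MTV is the
voxelized volume of the 10-mm tumor sphere.

```r
# simulate a cohort and fit the univariate Cox model for TAT HU
cohort <- simulate_cohort(cohort_spec(), seed = 20260101)
cox_regression(cohort, "tat_hu")
#>        model   term coefficient hazard_ratio    ci_lo    ci_hi      p_value   n
#> 1 univariate tat_hu   0.0758142     1.078762 1.033684 1.125806 0.0004993251 287
#>   n_events
#> 1       27
```

The fitted hazard ratio per 1-HU increase of TAT HU (1.08, 95% CI
1.03–1.13) recovers the programmed 1.10 within sampling error of a cohort
with 27 recurrences.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end and write their
tables under `results/`:

| script | what it does |
| --- | --- |
| `01_phantom_demo.R` | generates phantom cases, writes NIfTI + truth CSV, measures them |
| `02_simulate_cohort.R` | simulates the default cohort, baseline table |
| `03_survival_analysis.R` | full study: agreement, group comparisons, Cox models, cutoffs, KM, stratified recurrence |
| `04_hazard_recovery.R` | parameter-recovery experiment (60 replicate cohorts) |

`run_study(study_config(seed = ...))` performs the whole pipeline in one
call; `render_tables()` writes CSV/markdown/JSON reports with the config MD5
embedded, byte-identical on regeneration.

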
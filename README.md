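# lhmorph — whole left-heart morphometrics from 4D landmark clouds

`lhmorph` analyses the beating **left heart** — left ventricle (LV) and left
atrium (LA) acquired on the *same* heartbeat — as a single deforming shape.
It is aimed at researchers working with time-resolved endocardial landmark
clouds (e.g. from 3D speckle-tracking echocardiography, where each chamber is
sampled as 36 circles × 36 landmarks plus an apex, 1297 points per chamber and
2594 per frame) who want to compare *pure deformation* across subjects and to
quantify how the two chambers covary during the cardiac cycle.

## What it computes

Given per-subject cycles of landmark configurations with four annotated
electro-mechanical events (R peak, LV end-systole, mitral valve opening,
P peak), the pipeline:

1. **Homologous times** — each cycle is resampled at 16 physiologically
   matched phases: the 4 events plus 3 equally spaced times inside each
   inter-event gap, via periodic cubic splines on size-and-shape-aligned
   frames (`homologous_times()`, `interpolate_cycle()`).
2. **Linear-shift parallel transport** — each subject's 16 shapes are
   referred to its local template (the subject's Procrustes mean) and
   transported, by subtraction and addition in the tangent plane at the
   grand-mean common template CT, so that baseline inter-individual shape
   differences are filtered out and only deformations remain
   (`linear_shift()`).
3. **Trajectory attributes** — PCA of the transported shapes; each subject's
   motion trajectory is the 16 × 3 configuration of its first three PC
   scores, summarized by its centroid size CS, its end-diastole→end-systole
   chord angles in the PC1/PC2 and PC1/PC3 planes, and its trajectory-shape
   PC scores after a GPA across subjects; group contrasts are tested by
   permutation ANOVA / MANOVA on R² = SS_between / SS_total
   (`trajectory_attributes()`, `perm_anova()`).
4. **Covariation strength and direction** — per subject, a two-block PLS of
   the 16 LV vs 16 LA tangent shapes: the paired singular vectors (singular
   warps, SW) maximize inter-chamber covariance; strength is the permutation
   z-score of the first-pair correlation, direction is the **major-axis
   slope** of SW1_LA on SW1_LV (slope > 1: the LA changes shape faster per
   unit of LV shape change; slope = 1: isometry)
   (`two_block_pls()`, `pls_effect_size()`, `individual_covariation()`).
5. **Disintegration slope** — thin-plate-spline bending-energy decomposition
   at the CT; the OLS slope of log partial-warp variance on log bending
   energy is −1 for a self-similar shape series, more negative for more
   integrated series, near 0 for disintegrated ones
   (`bending_energy_basis()`, `disintegration_slope()`).
6. **Classification** — randomized-split evaluation of any attribute table
   with an RBF-kernel SVM (C = 1, per-class training draws, default 35/17
   leaving 10 + 3 test cases, 1000 repetitions), reporting mean AUC, total
   accuracy, specificity and sensitivity (`randomized_svm_eval()`).

Since clinical 3DSTE recordings of this kind are not publicly deposited, the
package ships a **synthetic 4D left-heart generator**
(`generate_cohort()`, `generate_cycle()`): two stacked quasi-ellipsoidal
chambers deforming periodically with a planted LA:LV shape-change rate,
subject-level baseline variation, frame jitter and landmark noise. Every
pipeline stage is validated against this generator's closed-form construction.

## Worked example

```r
library(lhmorph)

cohort <- generate_cohort(
  n_control = 12, n_hcm = 8,
  control_params = lh_params(n_circles = 12, n_per_circle = 12),
  hcm_params = lh_params(n_circles = 12, n_per_circle = 12,
                         lv_amplitude = 0.06, covariation_slope = 0.89),
  seed = 42)

report <- run_pipeline(cohort, seed = 42, n_perm = 999)
print(report)
```

```
left-heart pipeline report (seed 42 )
  trajectory CS by group:  Control 0.3323 | HCM 0.167   (perm-ANOVA R2 = 1 , p = 0.001 )
  MA slope by group:       Control 1.247 | HCM 0.893   (perm-ANOVA R2 = 1 , p = 0.001 )
  disintegration slope:    Control -1.038 | HCM -0.768   (p = 0.001 )
```

Reading the output: the Control group deforms more (larger trajectory
centroid size, planted amplitude 0.10 vs 0.06); the per-subject major-axis
slopes recover the planted LA:LV shape-change rates (1.25 and 0.89) — above
1, the atrium outpaces the ventricle, below 1 the reverse; both group
contrasts reach the permutation floor p = 1/(999+1). The disintegration
slopes are negative (integrated, smooth deformations); they differ here
because the groups were planted with different deformation amplitudes over a
fixed landmark-noise floor.

Per-subject tables are available from the report
(`report$trajectory$table`, `report$covariation`, `report$disintegration`),
and `write_lh_dataset()` / `read_lh_dataset()` move cohorts through the
long-form landmark CSV + events JSON interchange format.

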
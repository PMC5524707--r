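---
title: "Whole left-heart morphometrics: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole left-heart morphometrics: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhmorph)
```

# The problem

Echocardiographic speckle tracking yields, per heartbeat, a time series of
endocardial landmark clouds: here 1297 presumed-homologous points per chamber
(36 horizontal circles of 36 landmarks plus the apex), 2594 for the left
ventricle (LV) and left atrium (LA) digitized on the same clip. Two obstacles
stand between such data and a cross-subject statistical analysis of *motion*:

* frames fall at device-specific times, so cycle phases are not comparable
  across subjects; and
* subjects differ far more in baseline anatomy than in how they deform, so a
  naive pooled shape analysis measures anatomy, not function.

`lhmorph` addresses the first with interpolation at electro-mechanically
homologous times and the second with linear-shift parallel transport of each
subject's within-cycle deformations to a common template. On the transported
data it quantifies trajectory attributes, LV–LA covariation (strength and
direction), thin-plate-spline disintegration, and classification value.

# Models and procedures

## Shape spaces and superimposition

A configuration is a $k \times 3$ matrix. Centroid size is
$\mathrm{CS}(X) = \sqrt{\sum_i \lVert x_i - \bar x \rVert^2}$. Generalized
Procrustes analysis (`gpa()`) iteratively aligns configurations to their
evolving mean, either in *shape space* (translation, rotation, and scaling to
unit CS removed) or in *size-and-shape space* (SSS; translation and rotation
only). Reflections are excluded everywhere — anatomical landmark sets have a
fixed chirality — so rotations live in $SO(3)$, obtained by the
singular-value construction with the smallest singular value sign-flipped
when needed. The Procrustes (geodesic) distance between unit-size pre-shapes
is $\rho = \arccos(\sigma_1 + \sigma_2 \pm \sigma_3)$; because the two
leading singular values always dominate the third, $\rho \le \pi/2$ even
without reflections, the bound attained by a labelled planar triangle and
its mirror image.

Convergence: iteration stops when the root-mean-square displacement of the
consensus drops below $10^{-8}$ (at most 200 iterations), with the consensus
re-normalized to unit CS in shape space. Configurations with
$\mathrm{CS} < 10^{-12} \times$ the coordinate scale are rejected as
degenerate. The GPA stopping rule and the exclusion of reflections are this
package's choices; the procedure is otherwise the standard one.

## Homologous times

Four strictly homologous events anchor each cycle: R wave peak,
LV end-systole, mitral valve opening, P wave peak. Between consecutive
events (cyclically, wrapping the last gap to the first event plus one cycle)
three equally spaced times are inserted, giving 16 homologous times starting
at the R peak. Each subject's observed frames are first aligned by GPA in
SSS — size still carries information at this stage — and each landmark
coordinate is then interpolated by a *periodic* cubic spline over one cycle
(the heartbeat is cyclic; the boundary condition is this package's choice)
and evaluated at the 16 times. Index 1 (the R peak) is treated as
end-diastole, index 5 (LV end-systole) as end-systole throughout.

## Linear-shift transport

Per subject, shape-space GPA of its 16 shapes yields aligned unit-size
shapes and the local template (LT, the subject's mean shape). The common
template (CT) is the shape-space grand mean of all shapes of all subjects.
Each subject's LT is rotated onto the CT and the *same* rotation is applied
rigidly to its 16 shapes — one rotation per subject, so within-cycle
deformations stay mutually coherent (rotating each time frame independently
would be an equally defensible reading; the single-rotation variant is used
because it cannot re-absorb deformation into per-frame rotations). All
shapes are projected orthogonally onto the tangent plane at the CT
($v = x - \langle x, p\rangle p$; the linear projection is what makes
"transport by subtraction and addition" exact arithmetic), and each
subject's **tangent mean** is subtracted. Subtracting the tangent mean
rather than the projected LT makes every transported cycle centred on the CT
to machine precision (the two differ only by the $O(\rho^2)$ normalization
of the mean shape). The residuals are the pure deformations; transported
shapes are $CT + \text{residual}$.

The linear shift is a first-order approximation to transport along
geodesics; the package's tests verify that it agrees with a direct
re-centring oracle to a relative error that shrinks linearly with
deformation size (e.g. $3\times10^{-5}$ at deformations of $10^{-4}$ CS).
Cardiac deformations live at $\sim 0.1$ CS, where the approximation error is
at the percent level and identical in structure across subjects, which is
why it does not disturb group comparisons.

## Trajectories and their attributes

PCA over all transported shapes (deterministic sign convention: each
loading's largest-magnitude entry is positive, so angles are reproducible)
gives per-subject trajectories: the 16×3 configuration of PC1–PC3 scores.
Using exactly three PCs keeps trajectory shapes representable; the dominant
PC typically carries the alternating systo-diastolic LV–LA contraction.
Attributes:

* **size** — centroid size of the trajectory configuration;
* **orientation** — angles of the end-diastole→end-systole chord in the
  PC1/PC2 and PC1/PC3 planes (two-argument arctangent, degrees, from the
  chord, not from a regression fit);
* **shape** — PC scores after shape-space GPA of the trajectory
  configurations.

Group tests use permutation ANOVA (scalars) and permutational MANOVA
(aligned trajectory coordinates; a parametric MANOVA is unusable at
$p \gg n$): $R^2 = SS_{between}/SS_{total}$, p-value from label shuffles
with the observed statistic included in the null set (9999 permutations by
default, seeded). Angles enter the ANOVA as linear quantities; a circular
ANOVA was deliberately not substituted, to keep the attribute definitions
aligned with how the chord angles are constructed and reported.

## Covariation: strength and direction

Within each subject, the 16 transported LV shapes and 16 LA shapes form two
blocks. Two-block PLS (`two_block_pls()`) takes the SVD of their
cross-covariance — computed through the thin SVDs of the blocks, so
$p, q \gg n$ costs nothing — giving paired singular warps that maximize
inter-chamber covariance. Strength is a permutation z-score: rows of one
block are permuted (999 draws at the subject level, where the permutation
space over 16 rows is ample), and
$z = (r_{obs} - \overline{r_{perm}})/\mathrm{sd}(r_{perm})$ on the raw
first-pair correlation (no Fisher transform: with $n$ fixed at 16 for every
subject, comparability across subjects does not require it). Blocks are
centred but not column-standardized — shape coordinates share units.

Direction is the major-axis slope of SW1_LA on SW1_LV: the first eigenvector
of the 2×2 covariance of the paired scores. MA regression is used because
it is symmetric (orthogonal residuals), matching the symmetry of PLS; its
sign follows the covariance. Slope 1 is isometry of the two chambers' shape
change rates; above 1 the LA outpaces the LV. Singular-vector signs are
fixed (largest LV loading positive, LA vector tied to a non-negative
singular value) so slopes are reproducible. Group comparison of per-subject
slopes and z-scores uses the permutation ANOVA above. At the second-order
(trajectory-shape) level, PLS runs across individuals within each group and
group differences in z and slope are assessed by permuting group labels.

## Disintegration

For a reference shape (the CT — one shared basis keeps subjects comparable;
a per-subject reference would confound slope differences with basis
differences), the thin-plate-spline bending-energy matrix is built from the
3D biharmonic kernel $U(r) = -r$ (the 2D $r^2\log r$ kernel does not apply
in 3D) and eigen-decomposed: $k-4$ partial warps with positive bending
energy, orthogonal to the affine subspace. Per subject, the variance of
each warp's score across its 16 transported shapes (summed over the three
axes) is regressed — log variance on log bending energy — over warps above
a relative variance floor of $10^{-15}$ (a numerical guard against
log-of-zero). Slope −1 marks a self-similar series; more negative, more
integrated; near 0, disintegrated.

## Classification and reproducibility

`randomized_svm_eval()` repeatedly draws the stated per-class training
counts (default 35 Controls + 17 HCM, leaving 10 + 3 test cases, 1000
repetitions), standardizes features with training-split statistics only (no
test-set leakage), fits an RBF-kernel SVM with $C = 1$ and bandwidth
$\gamma = 1/d$ on the standardized features (the cost is the only kernel
parameter fixed by the protocol; the bandwidth convention is this
package's), and averages AUC (HCM-positive decision scores), total accuracy,
specificity (Control) and sensitivity (HCM) over repetitions.

For replica acquisitions of one subject, `coefficient_of_variation()`
summarizes paired replica differences as $100\cdot\mathrm{sd}/\mathrm{mean}$
of the absolute differences, and `replica_cycle_distance()` reports the
Procrustes distance between the replicas' trajectory shapes normalized by
its tangent-space maximum $\pi/2$.

# The synthetic generator

`generate_cohort()` emulates the acquisition the analysis expects, with
defaults chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_circles`, `n_per_circle` | 36, 36 | chamber sampling; 1297 landmarks/chamber |
| `lv_amplitude` | 0.10 (Control), 0.06 (HCM) | LV deformation, fraction of configuration CS |
| `covariation_slope` | 1.25 (Control), 0.89 (HCM) | planted LA:LV shape-change rate |
| `mode_mix` | 0.25 affine / 0.75 non-affine | deviatoric stretch vs tapered squeeze |
| `subject_shape_sd` | 0.03 | sd of the random linear baseline warp |
| `landmark_noise_sd` | 0.15 | per-coordinate noise, device units (radii ≈ 25) |
| `beat_rate_mean`, `beat_rate_sd` | 77, 13.16 | beats/min |
| `frame_interval_ms` | 41.6 | nominal frame spacing, 5% jitter |
| `event_phase_fractions` | 0, 0.35, 0.45, 0.85 | R, end-systole, MVO, P phases |

The chambers are a prolate (LV, semi-axes 25/25/45) and an oblate (LA,
25/25/18) surface stacked base-to-base across a shared annulus plane, so the
left heart is one connected cloud. Activation is a smooth periodic bump at
end-systole minus a bump at the P peak: the LV contracts in systole, the LA
(moving in exact anti-phase, amplitude `covariation_slope` times the LV's)
contracts at atrial systole. The event phases (end-systole at 35% of the
cycle, mitral valve opening shortly after at 45%, P peak at 85%) are
physiologically ordinary values chosen once.

One design point deserves emphasis. Unit-size normalization spreads any
*global-scaling* content of a chamber-confined deformation field across both
chamber blocks, which would contaminate the planted LA:LV rate. The planted
fields are therefore built from components orthogonal to chamber scaling —
a traceless (deviatoric) elliptical stretch and a tapered radial/longitudinal
squeeze — plus a small explicit volume component (15% of the field norm) so
that the LV is genuinely most contracted at end-systole. With this
construction the full pipeline recovers planted slopes to within ±0.005 at
zero noise, and the recovery bias stays well inside the ±0.1 acceptance band
at the default noise level.

What the generator does *not* emulate: myocardial wall mechanics and
torsion, regional wall-motion abnormalities, tracking dropout and
non-Gaussian speckle artefacts, breathing drift, and valve-plane
discontinuities. Passing tests therefore demonstrate that the *estimators
recover what was planted under the stated statistical structure*, not that
the pipeline is robust to every artefact of clinical recordings.

# Numerical conventions and edge cases

* GPA: tolerance $10^{-8}$ RMS, 200-iteration cap, non-convergence is an
  error with the displacement trace attached.
* PCA/PLS sign fixing as above; repeated runs are bit-identical.
* Permutation p-values include the observed statistic in the null set:
  $p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$; never exactly zero.
* Major-axis slope: isotropic clouds (equal variances, zero covariance) are
  an error, not a silent 0 or 45°.
* Degenerate (motionless) trajectories are flagged; their CS is 0 and
  angles are `NA`; the chord angle errors only when explicitly requested.
* Zero-variance partial warps are dropped from the disintegration
  regression; fewer than 2 usable warps is an error.
* Identical replicas give a coefficient of variation of 0 with a
  `degenerate` attribute (the ratio is formally 0/0).
* Constant feature columns are dropped (with a message) before SVM fitting.

# Problem sizes used in the tests

The test suite exercises the full 36×36 chamber sampling where the claim is
about structure (landmark counts, the 1293-warp basis) and reduced samplings
(8×8, 12×12 circles, cohorts of 6–30 subjects) elsewhere: the estimators'
behaviour is identical in structure at any sampling, and the reduced sizes
keep the suite fast enough to run routinely. The acceptance script uses a
500-shape self-similar series on a 100-landmark reference and a 30-subject
full-scale cohort, the sizes at which the two benchmark constants (−1 and 1)
are pinned down to well within their ±0.05 tolerances.

# Known limitations

* Linear-shift transport is first-order; at deformation scales far above
  ~0.2 CS the tangent-plane arithmetic would start to distort deformations,
  and a geodesic transport would be preferable.
* The permutation MANOVA decomposes Euclidean sums of squares of aligned
  coordinates; it inherits the usual insensitivity to purely covariance
  (dispersion-shape) group differences.
* The per-subject PLS z-scores use 16 observations; they are comparable
  across subjects by construction but should not be read as absolute
  integration strengths.
* Trajectory angles are treated as linear quantities in the ANOVA; angle
  distributions straddling ±180° would need a circular treatment.
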
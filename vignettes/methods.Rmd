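---
title: "Elastic kVCT-MVCT registration: model, validation and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic kVCT-MVCT registration: model, validation and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In helical tomotherapy of lung cancer, a daily megavoltage CT (MVCT) is
acquired on the treatment unit and used to reposition the patient against
the planning kilovoltage CT (kVCT). Over a 5-6 week course, lung anatomy
changes substantially — mediastinal shift with tumour regression,
progressing atelectasis, resolving pleural effusion, weight loss — and a
rigid alignment cannot describe these changes. Estimating them requires a
deformable registration of each MVCT to the planning kVCT, and any such
registration must be validated before its deformation fields are trusted
for dose accumulation.

`mvctreg` implements both halves of that task: the registration engine and
the complete accuracy-assessment suite, plus a synthetic thorax phantom
with known ground truth so the whole pipeline can be exercised and tested
without patient data.

## Spatial model

The transformation mapping a reference (kVCT) physical point $p$ into the
MVCT frame is the sum of a global rigid map and a local free-form
deformation:

$$T(p) = R\,(p - c) + c + t + D(p), \qquad
  D(p) = \sum_{ijk} B_i(u)\,B_j(v)\,B_k(w)\ \phi_{ijk},$$

where $R$ is a rotation (Euler angles applied Z·Y·X) about the fixed-image
center $c$, $t$ a translation, and $D$ a tensor-product cubic B-spline over
a regular lattice of control-point coefficients $\phi_{ijk}$ (mm). The
lattice covers the fixed-image domain plus the one-point cubic support
margin on every side, so an all-zero lattice is exactly the identity and a
constant lattice is exactly that constant (partition of unity) — both are
asserted in the test suite against a dense basis-summation oracle.

The additive composition (`transform_point()`) means the elastic stage
refines the rigid alignment rather than being composed with it; the
displacement field is defined on the reference domain, which is also where
validation landmarks live.

## Similarity metric

Both stages minimise negative mutual information in the Parzen-window
form: the joint distribution over a set of fixed-image sample points uses
a zero-order (histogram) window along the fixed intensity axis and a cubic
B-spline window along the moving axis, making $-\mathrm{MI}$ continuously
differentiable in the mapped sample positions. The implementation (C++)
returns the analytic gradient with respect to those positions, which is
chained to the 6 rigid parameters or scattered onto the coefficient
lattice. Unit tests verify the value against an independent dense R oracle
(1e-8) and the gradient against central finite differences (relative 1e-4).

Choices that matter:

* **Bins**: 50 per image (the canonical value for this metric family);
  configurable via `mi_config()`. A consequence worth knowing: intensity
  structure smaller than one bin width (~35 HU over a thorax range) is
  invisible to the metric.
* **Sampling**: the metric is evaluated on a random subset of body voxels,
  drawn once per level from a seeded RNG (deterministic end to end).
  Samples whose mapped position leaves the moving image are dropped and
  the distribution renormalised; if usable samples fall below
  `min(min_samples, 25%)` of the draw the stage aborts with a diagnostic —
  this is precisely the failure mode the axial pre-cropping exists to
  prevent.
* **Degenerate partners**: a spatially constant moving image yields
  MI = 0 by convention rather than an error.

## Multi-resolution schedules

**Rigid** (3 levels): image pyramid with shrink factors 4/2/1 (capped so no
axis drops below 8 voxels) and matched Gaussian pre-smoothing; regular-step
gradient descent on the 6 parameters with rotations scaled at 1 rad ≡ 50 mm
so the step length is commensurate across parameters. Steps move against
the normalised gradient, are halved whenever the metric fails to decrease,
and terminate at the level's minimum step (1e-2, 5e-3, 2.5e-3 mm). The
sampling percentages (100/50/25% per level) are a package choice; on
noise-free phantoms this recovers 10 mm translations and 5° rotations to
well under half a voxel and half a degree.

**Elastic** (4 levels, `elastic_schedules()`): multi-resolution is
expressed through blur, sampling percentage and lattice spacing — the
images are never down-sampled. Per level:

| level | kernel (voxels) | sampled voxels | L-BFGS-B tolerance | grid (mm) |
|---|---|---|---|---|
| 1 | 16 | 0.8% | 1e-5 | 96 |
| 2 | 8 | 3.4% | 1e-6 | 64 |
| 3 | 2 | 9.3% | 1e-7 | 45 |
| 4 | 0 | 19.7% | 1e-8 | 30 |

The kernel values are *support widths* in voxels; smoothing uses a
separable Gaussian of standard deviation width/4 (a ±2 sd support). We
initially implemented the width values directly as standard deviations and
found level-1 images blurred to near-uniformity (a 16-voxel sd is 16-52 mm
depending on axis), with the level-1 optimisation then free to introduce
large spurious deformations; width/4 gives the conventional pyramid blur
(≈ 4 mm sd on a typical kVCT) and stable coarse levels. The axial kernel
is halved at the two coarse levels when a volume's axial voxel size is
smaller than its in-plane size; each image is judged by its own spacing.

The lattice starts at ≈ 96 mm spacing and is refined to 64 → 45 → 30 mm
(geometric interpolation between the coarsest and finest resolutions).
Refinement (`refine_bspline_grid()`) re-fits the finer lattice to the
coarse displacement field by separable least-squares collocation (four
samples per new interval per axis); dyadic refinements reproduce the field
to numerical precision, and arbitrary refinements to well under 0.05 mm.
Refinement is per-axis monotone: an axis whose cropped extent already
forces a spacing below the requested level value keeps its grid rather
than erroring — short cropped z-extents commonly hit this between the
96 mm and 64 mm levels.

Coefficients are optimised by bounded L-BFGS-B (`stats::optim`; memory 10,
±60 mm box bounds, ≤ 500 iterations/level) to the level's
projected-gradient tolerance. An occasional `ABNORMAL_TERMINATION_IN_LNSRCH`
on noisy data comes from the metric's kinks where samples cross the moving
boundary; it is treated as benign when the level still decreased the
metric, and reported in the per-level diagnostics otherwise.

**Sample-count floor.** Elastic levels draw
`max(level %, min_draw)` points, with `min_draw = 7000` — the absolute
count the 0.8% coarse level draws on a clinical-size body (~900k voxels).
On small volumes the percentage alone would draw a few hundred points and
the coarse-level FFD overfits the Parzen histogram, drifting several mm on
*identical* image pairs; the floor removes this scale artifact and is
inactive at clinical sizes.

## Pre-processing

Three steps precede registration: (1) couch suppression — any
above-threshold connected component whose centroid lies in the posterior
15% band of the y extent and that is detached from the main component is
removed (a reproducible automation of a manual step); (2) body masking —
threshold at −400 HU, largest 6-connected 3D component, slice-wise 2D hole
filling (so lungs belong to the body), background set to −1000 HU; (3)
axial cropping of the kVCT to the MVCT extent, keeping slices whose
physical z center lies inside the MVCT's half-open z interval — a
deterministic reading of "avoid samples falling outside the MVCT domain".

## Validation suite

* **Correlation coefficient**: Pearson correlation over the common grid
  excluding a 30-voxel x/y border and 2 end slices (regions interpolated
  from outside the volume carry no information). On grids smaller than
  ~128 voxels the borders are capped at dim/4 and dim/8 so an interior
  remains.
* **Landmark TRE**: landmarks identified in the kVCT frame are mapped by
  `transform_point()` and compared with their independently known MVCT
  positions; per-landmark Euclidean distance with mean, sample SD and
  maximum. Out-of-domain landmarks are reported as exclusions, never
  silently dropped. Per-session visibility is an explicit inclusion list.
* **Lung segmentation**: slice-wise region growing under a −1000 to
  −500 HU window; regions reachable from the exterior air at the slice
  border are discarded, in-body regions kept, holes (vessels) filled in
  2D, slices piled into the binary volume. Seeding is automated (every
  in-window, in-body, non-border-connected voxel); the thresholds are the
  standard ones for both modalities, which presumes HU-calibrated MVCT.
* **Correspondence**: per lung (split by 3D components, left/right by
  centroid x in patient orientation, fused lungs split at the body's
  mid-sagittal plane), restricted to the commonly imaged z interval:
  percent volume error $V_E = 100\,(V^{CT}-V^{reg})/V^{CT}$, centroid
  distance $C_E$ (mm), and Jaccard overlap. The $V_E$ sign/normalisation
  convention is pinned by the published worked example (632.39 vs
  475.22 cm³ → 24.85%).
* **Cohort statistics**: per-patient TRE summaries are the mean/SD of the
  session means and the max of maxima; cohort lung summaries pool |V_E|,
  C_E and JAC over both lungs and all sessions. Rigid-vs-elastic
  differences use the paired Wilcoxon signed-rank test: zeros dropped,
  average ranks for ties, exact tail (`psignrank`) for untied n ≤ 25,
  exact-by-enumeration (all $2^n$ sign patterns over midranks) for tied
  n ≤ 15, tie-corrected normal approximation otherwise. Sample (n−1) SDs
  throughout.

The package bundles an example cohort (five patients, three MVCT sessions
each) as pure per-session data; `aggregate_cohort()` reproduces every
cohort-level figure from those rows, and the acceptance tests assert the
key cells.

## The phantom and what it does (not) show

`generate_thorax_phantom()` builds an ellipsoidal soft-tissue body with two
ellipsoidal lungs, a vertebral bone column, a basal pleural-effusion layer
in the left lung, a detached couch slab, band-limited intensity texture,
and eleven anatomical landmarks (carina, bronchial bifurcations, vertebral
bodies, aortic arch, lung apices, breast-bone, ribs) rendered as
3-voxel-radius +300 HU spheres; residuals always use the analytic centers,
never re-detected positions. Default geometry matches a thoracic planning
kVCT (192 × 192 × 60 at 0.976 × 0.976 × 3.27 mm); the test suite uses a
64 × 64 × 32 grid at 3 × 3 × 5 mm with proportionally scaled anatomy to
keep runtimes in seconds.

Texture defaults to an 80 HU standard deviation, smoothed over ~2 voxels:
the scale of vascular/parenchymal contrast. This matters: texture much
below one histogram bin (~35 HU) leaves tissue interiors invisible to the
metric, and the unconstrained FFD then wanders on the resulting plateaus.
Values are clamped at −1000 HU, the physical floor of the scale.

Deformations (`deformation_spec()`) are sums of compactly supported smooth
bumps, multiplied by an image-boundary taper so displacement is exactly
zero at the boundary: lateral mediastinal shift; atelectasis as a radial
contraction of the left lung calibrated so a requested percent volume loss
is met; pleural-effusion resolution (basal layer re-aerated to lung HU
plus a downward interface bump); body shrink (inward surface shell, width
0.5 in normalised radius so the finest 30 mm lattice can represent it);
and a generic smooth random field. The deformed image is synthesised by
fixed-point inversion of the forward map (convergent for these smooth
contractions); foldover is rejected by a positivity check on the dense
Jacobian determinant. Ground truth (advected landmarks, dense forward
field, true lung masks in both frames) is updated analytically and is
self-consistent to 1e-6 mm.

The default validation scenarios superimpose a 10 mm smooth random
background field on each mode-specific change, emulating the posture and
free-breathing differences that accompany any repeat acquisition. Without
it, modes that barely move most landmarks leave the rigid stage at a
sub-millimetre TRE floor that the elastic stage can only match, not beat —
a situation the clinical cohorts this emulates do not present.
`degrade_to_mvct()` then resamples to MVCT spacing (0.754 × 0.754 × 4 mm),
restricts the axial field of view (70% centrally by default), scales
contrast by 0.9 about air and adds 30 HU Gaussian noise.

What passing phantom tests show: the optimiser recovers smooth, invertible,
moderate-amplitude fields through genuine MVCT-like degradation, and every
validation metric behaves and orders as expected. What they do not show:
performance under reconstruction artifacts, breathing motion within a
scan, HU-miscalibrated MVCT, sliding interfaces (the pleura slides in real
patients; smooth FFDs cannot represent the discontinuity), or
non-diffeomorphic change such as appearing/disappearing tissue — the
effusion scenario deliberately includes an intensity change no deformation
can explain, and the registration treats it as the nuisance it is
clinically.

## Numerical choices and degenerate inputs

* Trilinear interpolation with −1000 HU out-of-domain fill for all image
  warping; the "registered MVCT" is the MVCT resampled on the (cropped)
  kVCT grid.
* Gaussian smoothing is separable, truncated at 3 sd, with edge
  replication (constants are preserved exactly); a zero width on an axis
  disables filtering there.
* Determinism: every stochastic step (sampling, phantom texture, MVCT
  noise) is seeded; identical configuration and seed reproduce transforms
  and metrics bitwise. Schedules, seeds and a configuration hash are
  embedded in each study's provenance.
* Degenerate inputs error early and descriptively: all-air images (no
  body), empty axial overlap, empty segmentations, empty masks in overlap
  metrics, all-zero Wilcoxon differences, out-of-support B-spline
  evaluation.

## Problem sizes used by the tests

The suite registers 64 × 64 × 32 phantoms (≈ 130k voxels, ≈ 35k body
voxels): a rigid stage takes ~0.5 s and a full rigid+elastic study ~10-20 s
on one core, so the complete suite, including a four-scenario validation
run, completes in a few minutes. The defaults (`phantom_spec()`,
clinical-size grids) run the same code path in minutes per study.

## Known limitations

* No regularisation term on the FFD beyond the multi-resolution schedule,
  box bounds and sampling; no guarantee of invertibility of *estimated*
  fields (ground-truth fields are checked).
* Axis-aligned geometry only (no oblique direction cosines or gantry
  tilt); single frame of reference.
* MVCT must arrive HU-calibrated for the segmentation thresholds to be
  meaningful; the metric itself tolerates monotone intensity remapping.
* The Wilcoxon enumeration path is exponential and capped at n = 15 with
  ties; larger tied samples use the normal approximation.
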
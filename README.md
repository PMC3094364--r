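# mvctreg

Elastic registration of daily megavoltage CT (MVCT) to the planning
kilovoltage CT (kVCT) in helical tomotherapy of lung cancer, together with
the complete accuracy-assessment methodology needed to trust the resulting
deformation fields.

**Who it is for.** Medical physicists and image-analysis researchers who
need to (a) estimate lung-parenchyma deformation between a planning kVCT
and daily MVCTs acquired in the treatment position, and (b) quantify how
good that estimate is — per study, per lung, and across a cohort.

## The method

The spatial model is a sum of a global rigid transformation and a local
elastic deformation,

    T(p) = R (p − c) + c + t + D(p),

where `D` is a free-form deformation: a tensor-product **cubic B-spline**
over a regular lattice of control points. Both stages minimise negative
**mutual information** in the Parzen-window ("Mattes") form — zero-order
window on the fixed intensities, cubic window on the moving ones — with
analytic gradients, so the method works across the kVCT/MVCT contrast
gap. The rigid stage uses a 3-level image pyramid with regular-step
gradient descent (step lengths 1e-2, 5e-3, 2.5e-3 mm); the elastic stage
uses a 4-level schedule of Gaussian blurs (16/8/2/0-voxel kernels),
sampling percentages (0.8/3.4/9.3/19.7%), L-BFGS-B tolerances
(1e-5…1e-8) and control-grid spacings (96 → 64 → 45 → 30 mm).

Validation follows the standard suite for this problem: border-trimmed
Pearson correlation (CC), landmark target registration error (TRE, mm),
slice-wise region-growing lung segmentation in the −1000…−500 HU window,
per-lung volume error `V_E = 100 (V_CT − V_reg)/V_CT`, centroid error
`C_E` (mm) and Jaccard overlap on the commonly imaged sub-region, cohort
aggregation, and paired Wilcoxon signed-rank comparisons of the rigid and
elastic stages.

Because clinical image pairs cannot be bundled, the package ships a
**synthetic thorax phantom** with HU-calibrated anatomy, ground-truth
smooth deformations for the clinically observed change taxonomy
(mediastinal shift, atelectasis, resolving pleural effusion, body shrink),
MVCT-style degradation (0.754 × 0.754 × 4 mm resampling, restricted axial
field of view, contrast scaling, 30 HU noise), and analytic landmarks —
so every stage is testable end to end.

## Worked example

```r
library(mvctreg)

# a small thorax phantom (3 x 3 x 5 mm voxels to keep this quick)
spec <- phantom_spec(dims = c(64, 64, 32), spacing = c(3, 3, 5),
                     body_semiaxes = c(70, 55, 110),
                     lung_semiaxes = c(22, 34, 58),
                     lung_offset = c(30, -4, 0), bone_radius = 10, seed = 4)
ph  <- generate_thorax_phantom(spec)

# known anatomy change: mediastinal shift + distributed posture field
def  <- apply_synthetic_deformation(ph$image, ph$truth,
          deformation_spec("mediastinal_shift", background_amplitude = 10))
mvct <- degrade_to_mvct(def$image, spacing = c(2.5, 2.5, 4),
                        fov_z = c(15, 145), seed = 7)

study <- run_study(study_config(fixed = ph$image, moving = mvct, seed = 11))
study
#> <study_result> patient 1 session 1
#>   stage      cc
#> 1 rigid   0.894
#> 2 elastic 0.932
#>   stage   lung  v_ct_mm3 v_reg_mm3 ve_percent ce_mm   jac
#> 1 rigid   left    153180    134190     12.4   2.56  0.830
#> 2 rigid   right   179955    204930    -13.9   3.05  0.859
#> 3 elastic left    153180    140265      8.43  0.788 0.903
#> 4 elastic right   179955    180855     -0.500 0.543 0.954

ground_truth_error(composite_transform(study$transform_rigid), def$truth)
#> <tre> n = 11: mean 3.23 +/- 2.15 mm, max 6.19 mm
ground_truth_error(study$transform, def$truth)
#> <tre> n = 11: mean 1.48 +/- 0.69 mm, max 2.78 mm
```

Reading the numbers: the rigid stage aligns the bodies but cannot follow
the anatomy change — lung volumes disagree by 12–14%, centroids by
2.5–3 mm, and the ground-truth landmark error is 3.2 mm on average. The
elastic stage recovers the deformation: CC rises to 0.93, volume errors
drop well below 10%, centroid errors under 1 mm, Jaccard overlap above
0.9, and the mean landmark error falls to 1.5 mm — below the 5 mm voxel
size, which is the accuracy scale this class of method is expected to
reach.

Cohort-level use follows the same grammar: `run_cohort()` collects
per-session metrics and `aggregate_cohort()` computes the per-patient and
cohort summaries plus the rigid-vs-elastic Wilcoxon tests.
`run_phantom_validation()` runs the whole four-scenario synthetic
evaluation. `tidy()`/`glance()` expose every result as tibbles;
`autoplot()` and `plot_difference()` draw slices and difference images.

A thin command-line front end (`inst/cli/mvctreg.R`) exposes
`register`, `metrics`, `phantom`, `cohort` and `tables-check`
subcommands over the same functions.

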
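# octvbm — voxel-based morphometry for macular OCT thickness maps

`octvbm` detects and localizes *focal* retinal neurodegeneration that global
or sector-averaged OCT parameters miss. It spatially normalizes macular
layer-thickness maps (RNFL, GCIPL, INL, Retina) into a common target space
and runs voxel-wise statistics across subjects, with full multiplicity
control, percentage-change mapping, covariate regression, and voxel-wise
test–retest reliability mapping. It is aimed at neuro-ophthalmology and
neuroimmunology groups analysing cohorts of segmented macular volume scans
(e.g. 25 B-scans × 1024 A-scans over 20° × 20°).

## The method in brief

**Spatial normalization.** Each scan is mirrored to left-eye orientation
(optic nerve head on the left), the fovea is located as the thinnest point
of the Retina map (NA-aware Gaussian smoothing in physical units, then
argmin with centroid tie-break), a global integer 2D translation aligns the
subject fovea to the target fovea, and a per-A-line 1D affine
*z* → *a z* + *b* maps the subject's ILM and BM depths exactly onto the
target's. One shared transform per scan is applied to all four layer maps.
Thickness values are never interpolated or rescaled by the depth affine, so
total retinal thickness remains a valid downstream covariate.

**Voxel-wise inference.** At every grid cell *v* outside a 500 µm central
fovea exclusion:

    thickness_v = β₀ + β₁·group + β₂·age + β₃·sex + β₄·retina_v + ε

Group effects are tested by t contrast (or omnibus F across groups), raw p
values are corrected by Benjamini–Hochberg FDR over all valid voxels of the
map (α = 0.05), and significant components smaller than 9 voxels (3 × 3
footprint, 8-connectivity) are removed by the cluster-extent filter.
Percentage change is `(patient − HC) / HC × 100` per voxel; covariate
effects (age, disease duration, EDSS) are mapped as standardized regression
coefficients through the same correction chain.

**Reliability.** From repeated same-day scans: per-voxel within-subject SD
(Sw), coefficient of variation (CV = Sw / grand mean × 100), and ICC from
the two-way random-effects decomposition (absolute agreement, single
measurement), plus the voxel-wise paired t retest null check and scalar
reliability of summary parameters.

**Synthetic ground truth.** A seeded phantom generator (foveal pit, RNFL
gradient toward the optic nerve head, perifoveal GCIPL annulus, fovea
jitter, effect footprints, Gaussian measurement noise, retest variance
components) makes every stage testable without patient data. See the
methods vignette (`vignettes/vbm-oct-methods.Rmd`) for the models,
assumptions, and limitations.

## Worked example

Simulate a two-group cohort with a −5 µm GCIPL atrophy disc (radius 8
voxels) injected into the patient group, register everything, and run the
voxel-wise comparison:

```r
library(octvbm)

geom <- oct_geometry(n_ascans = 128L)          # compact grid for the demo
template <- make_template(template_spec(geometry = geom))
atrophy <- effect_spec("GCIPL", delta_um = -5, shape = "disc",
                       center = template$fovea_center + c(0, 32),
                       radius_vox = 8)
cohort <- make_cohort(template,
                      groups = list(list(label = "HC",  n = 30),
                                    list(label = "RMS", n = 30,
                                         effects = list(atrophy))),
                      seed = 1)

target <- build_target(list(template), policy = "designated-reference")
registered <- lapply(cohort$subjects, function(s)
  register_scan(s$maps, s$boundaries, target)$maps)

gcipl  <- build_group_stack(lapply(registered, `[[`, "GCIPL"),  cohort$covariates)
retina <- build_group_stack(lapply(registered, `[[`, "Retina"), cohort$covariates)
mask   <- fovea_exclusion_mask(target, radius_um = 500)
result <- voxelwise_glm(gcipl, retina, glm_spec(), mask = mask)

result
#> voxel-wise two-group-t map: 25 x 128, 197 significant voxels in 1 cluster(s) (alpha 0.05, min extent 9)
result$cluster_table
#>   label size centroid_row centroid_col
#> 1     1  197           13           96
round(c(q_threshold = result$q_threshold,
        mean_diff_um = mean(result$diff[result$sig])), 4)
#>  q_threshold mean_diff_um
#>       0.0027      -5.1947
```

The injected disc (197 voxels centred at row 13, column 96) is recovered as
a single significant cluster at exactly that position, and the mean
difference inside it matches the injected −5 µm. `render_overlay(result,
result$diff, color_range = 5, file = "overlay.png")` paints the significant
voxels over a fundus background with a diverging ±5 µm colormap.

Scalar test–retest reliability of a derived macular volume:

```r
retest <- make_retest(template, n_subjects = 10, between_sd_um = 2.5,
                      within_sd_um = 1.5, seed = 2)
vols <- apply(retest$data, c(1, 2), function(m)
  macular_layer_volume(thickness_map(matrix(m, 25, 128), "GCIPL", "L", geom)))
scalar_reliability(vols)
#> $sw  0.00115   $cv  0.0448   $icc  0.802   $classification  "good"
```

A thin command-line front-end (`inst/exec/octvbm`) wraps the same functions:
`octvbm simulate --preset atrophy-disc --seed 1 --out data/`, then
`octvbm run --in data/ --out results/`.

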
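---
title: "Voxel-based morphometry for macular OCT: models and methods"
author: "octvbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based morphometry for macular OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octvbm)
```

## Why voxel-wise retinal mapping

Standard optical coherence tomography (OCT) outcome measures — global
peripapillary RNFL thickness, macular layer volumes, ETDRS sector means —
average away spatial information. Focal neuro-axonal loss, such as the
perifoveal ganglion-cell atrophy seen early in demyelinating disease, can be
invisible to a sector mean while being highly structured in space. `octvbm`
transfers the logic of voxel-based morphometry to the macula: every
individual layer-thickness map is brought into a common anatomical space,
and statistics are computed independently at every grid cell ("voxel" here
means one en-face grid cell of a thickness map), with principled control of
the resulting multiplicity.

The package operates on *segmented* inputs — en-face grids of layer
thickness in micrometres, or boundary-surface depth grids from which
thicknesses are differenced — for the four standard maps: RNFL, GCIPL, INL,
and Retina (ILM to Bruch's membrane). Automatic layer segmentation is out of
scope; any segmentation pipeline that can export boundary depths or
thickness grids in a portable format (tab-separated text, float-TIFF or
NIfTI, each with a JSON sidecar) can feed it.

## Spatial normalization

Registration is deliberately low-parametric, exploiting the fact that all
scans follow one acquisition protocol (by default 25 B-scans x 1024 A-scans
over a 20 x 20 degree field centred on the fovea):

1. **Left-eye normalization.** Right-eye scans are mirrored along the A-scan
   axis so the optic nerve head is on the left in every subject. Mirroring
   permutes columns only; values are untouched.
2. **Fovea landmark.** The fovea is the thinnest point of the Retina map.
   The map is smoothed with a small Gaussian before the argmin, and exact
   ties are resolved by the centroid of the minimum set rounded to the
   nearest grid point.
3. **Global 2D translation.** The integer grid shift that puts the subject
   fovea on the target fovea is applied to all four layer maps of the scan
   (one shared transform per scan). Cells translated in from outside the
   acquired field are invalid (`NA`), never zero.
4. **Per-A-line 1D depth affine.** At every A-line, the affine map
   `z -> a z + b` is fitted through the two anchor surfaces, taking the
   subject's ILM and BM depths exactly onto the target's. The fit is closed
   form and exact at both anchors.

Two design points deserve emphasis.

**The smoothing width is physical, not voxel-based.** The acquisition grid
is strongly anisotropic: ~240 um between B-scan rows versus ~5.6 um between
A-scan columns at native resolution. A "1-voxel" isotropic smoothing kernel
therefore smooths 240 um worth of anatomy along rows but barely 6 um along
columns, and near the flat floor of the foveal pit the unsmoothed column
profile changes by far less than the measurement noise between adjacent
columns — the raw argmin wanders along the column axis. `detect_fovea()`
takes its width in micrometres (default `sigma_um = 250`, about the half
width of the foveal floor) and converts it to per-axis voxel sigmas, which
makes localization stable under noise at any grid resolution while leaving
noise-free detection exact. Smoothing is NA-aware (normalized convolution),
so invalid cells neither bleed values nor bias edges.

**The depth affine aligns coordinates, not values.** The per-A-line scale
`a` describes how the subject's retinal depth span maps to the target's; it
is stored in the transform, but thickness values are *not* multiplied by it
by default. Rescaling thickness by `a` would normalize away total retinal
thickness — yet total Retina thickness is entered as a GLM covariate
downstream, which is only meaningful if registration leaves it intact. The
alternative convention is available as `rescale_thickness = TRUE` for
sensitivity analyses.

The target space is, by default, a cohort mean template: all scans are
registered to a designated reference scan, the registered Retina and ILM/BM
grids are voxel-wise averaged, and the average defines the final target to
which every scan is then registered once more. A fixed reference scan can be
used instead (`target_policy = "designated-reference"`).

Translation is integer-valued (fovea aligned to the nearest voxel). This
keeps every surviving voxel's value bit-identical to its source — no
interpolation enters the statistics. At the native column spacing of ~5.6 um
the sub-voxel alignment error is negligible against the 240 um row spacing.

## Voxel-wise statistics

At every voxel `v` outside the central fovea exclusion (default radius
500 um, roughly the central ETDRS subfield, where layer boundaries are
poorly defined), the group comparison fits the general linear model

```
thickness_v = b0 + b1 * group + b2 * age + b3 * sex + b4 * retina_v + e
```

with the subject's Retina thickness *at that voxel* as a covariate, so that
layer-specific effects are distinguished from global thickness differences.
The group effect is tested by a t contrast (two groups, disease minus
reference) or by the omnibus F over the group dummies. Voxels with fewer
complete observations than model parameters + 1 (map borders after
translation) are excluded and reported in `n_effective`.

Multiplicity is controlled in two stages, each map being its own family:

* **Benjamini-Hochberg FDR** at `alpha = 0.05` over all valid voxels of the
  map (step-up; the realized p cutoff is reported). Each layer's comparison
  is corrected separately, matching how per-layer results are reported; the
  BH variant (not Benjamini-Yekutieli) is appropriate because neighbouring
  voxel statistics are positively dependent.
* **Cluster-extent filtering**: connected components of the surviving
  voxels (8-neighbour adjacency by default) smaller than
  `min_cluster_voxels = 9` are removed. The 9-voxel minimum corresponds to
  a 3 x 3 footprint; both the extent and the connectivity are configurable.
  Components are labelled in decreasing size, ties broken by the
  top-left-most voxel.

Two effect summaries are attached to every comparison. The `diff` map is the
*unadjusted* group mean difference in micrometres — this is what overlay
figures render, and it is deliberately not the adjusted coefficient: when an
injected or pathological layer change also moves total Retina thickness, the
retina-adjusted group coefficient is attenuated by construction, while the
raw difference preserves the physical magnitude. The adjusted coefficients
(and adjusted group means at covariate means) are available in `beta` and
`adjusted_means`. The percentage-change map is
`(mean_patient - mean_HC) / mean_HC x 100` per voxel.

Voxel-wise covariate regression (`voxelwise_regression()`) reports the
standardized regression coefficient — the slope between the z-scored
predictor and the z-scored per-voxel response, equal to Pearson's r in the
unadjusted case — followed by the same FDR + cluster procedure.

## Test-retest reliability mapping

For repeated same-day scans registered to the same target, per voxel:

* `Sw = sqrt( mean_i var_within_i )`, the within-subject SD; for two
  sessions this is `sqrt( sum d_i^2 / 2n )` with `d_i` the session
  difference of subject `i`.
* `CV = Sw / grand mean x 100` (the voxel's grand mean across subjects and
  sessions in the denominator, matching the Sw-based presentation).
* `ICC` from the two-way random-effects ANOVA decomposition; the default
  form is absolute agreement, single measurement —
  `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)` — because repeated
  scans of one device should agree in value, not merely rank subjects
  consistently. The consistency form (3,1) is available via `form`.
  Classification bands: >= 0.9 excellent, >= 0.75 good, >= 0.5 moderate,
  else poor.

`retest_paired_test()` runs the voxel-wise paired t between first and second
scans through the identical FDR + cluster chain; on a well-behaved scanner
nothing should survive. `scalar_reliability()` applies the same formulas to
scalar summaries (e.g. macular layer volumes) as a 1 x 1 grid, so the two
code paths cannot diverge.

## The synthetic phantom: what it emulates, and what it does not

Because patient-level OCT data cannot be redistributed, every stage is
validated against a synthetic cohort generator with known ground truth. The
phantom (`make_template()`) reproduces the gross features that the pipeline
actually exploits:

* the acquisition geometry (25 B-scans x 1024 A-scans, 20 x 20 degrees,
  240 um B-scan spacing; any grid can be configured);
* a foveal pit — a Gaussian-profile central thinning (default depth 120 um,
  radius 900 um) producing a unique Retina minimum at a known position;
* RNFL increasing toward the optic-nerve-head side (default 6 um/mm);
* a perifoveal GCIPL annulus (default +25 um at 1.5 mm eccentricity) and a
  milder INL annulus;
* a low-amplitude seeded smooth texture (0.2 um), damped inside the pit;
* boundary surfaces built cumulatively from the component thicknesses, so
  the anatomical surface order and the component-vs-total invariant hold by
  construction.

Subjects are drawn by integer fovea jitter (inter-subject fixation
variation), an optional per-subject multiplicative thickness scale (default
sd 0.03, emulating inter-subject anatomical variation and making the Retina
covariate informative), optional effect footprints (discs, annuli, sectors
with signed thickness deltas), and independent Gaussian measurement noise
per component layer (default sd 1.5 um, inside the sub-3-um within-subject
SD envelope reported for this class of scanner). Retest stacks use explicit
between-/within-subject variance components so the ground-truth ICC is
`sb^2 / (sb^2 + sw^2)` exactly.

What the phantom does **not** emulate — and hence what passing tests do not
demonstrate about real data: speckle and intensity artefacts, segmentation
failures correlated with pathology, spatially correlated measurement noise
(available only as a stress-test option), eye-motion distortion within a
scan, axial-length scaling differences between eyes, and real anatomical
covariance between layers. Validation on the phantom establishes that the
*estimators and corrections are implemented correctly and calibrated under
their assumptions*, not that those assumptions hold in any given clinic.

## Numerical and degenerate-input conventions

* Invalid cells are `NA` everywhere, never zero; zeros would bias group
  means and variance estimates. Readers mark non-finite and sentinel cells
  invalid on ingest.
* Degenerate A-lines (zero retinal span) are flagged invalid rather than
  producing infinite affine scales; zero-variance volumes, all-invalid maps,
  constant covariates and empty correction families raise explicit errors
  or warnings naming the problem.
* Ties in fovea detection resolve to the centroid of the minimum set,
  rounded to the nearest grid point.
* Per-voxel GLM fitting uses a vectorized least-squares path for voxels with
  complete data (the per-voxel Retina column is absorbed by
  Frisch-Waugh residualization with a Schur-complement correction of the
  common coefficients) and falls back to per-voxel complete-case QR fits
  where subjects are missing; both paths are cross-checked against `lm()`
  to 1e-10 in the test suite. Perfect fits with zero effect report t = 0,
  p = 1 rather than 0/0.
* Cluster labelling uses graph connected components over the significant
  voxels' adjacency; label order is decreasing size with a deterministic
  tie-break, so reruns are bit-identical.

## Validation problem sizes

The packaged validation (test suite and `scripts/acceptance.R`) runs the
full chain on a 25 x 128 crop of the native grid — same B-scan count and
field of view, coarser A-scan sampling — which preserves the anisotropy that
drives the design choices above while keeping simulations compact: 200
replicates of a two-group null (30 + 30 subjects) for false-discovery
calibration, 50 seeded jitter-recovery registrations, 20 random stacks for
the least-squares oracle, one 30 + 30 effect-recovery cohort with a -5 um
disc of radius 8 voxels, a 50-subject retest set with equal 5 um variance
components, and 100 null retest replicates of 10 subjects. All generators
are seeded and bit-reproducible.

## Known limitations

* Registration is translation-only en face; torsional or rotational
  misalignment between scans is not modelled (no deformable warping, by
  design).
* The 2D translation is estimated solely from the fovea landmark, taking
  the acquisition protocol's fovea-centred design literally; an
  intensity-driven refinement is out of scope.
* Inter-eye correlation under the eye-level policy is not modelled; the
  within-subject eye-averaging policy is the conservative default.
* Cluster-extent inference controls extent by a fixed minimum, not by
  permutation of cluster mass; spatial smoothing of statistic maps is
  intentionally absent.
* The percentage-change map divides by the control mean per voxel and is
  unstable where that mean approaches zero (e.g. foveal RNFL); such voxels
  are flagged invalid rather than clamped.
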
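---
title: "Methods: 3D pelvimetry from CT-like volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D pelvimetry from CT-like volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Pelvimetry3D reimplements a complete CT pelvimetry workflow — slice-wise
seeded segmentation of the bony pelvis, surface meshing with a
volume-audited smoothing step, fiducial-landmark measurement of 21
pelvimetric quantities, and the sex-stratified statistics built on them —
as tested, reusable code. Because clinical CT series of this kind are not
publicly deposited, the package also ships a calibrated synthetic-phantom
generator, so that every stage of the pipeline can be exercised and
verified without patient data. This vignette records the models,
parameter choices and numerical decisions behind each stage, and what the
synthetic evidence does and does not establish about real data.

## Coordinate conventions

All geometry lives in a right-handed LPS (left–posterior–superior)
patient frame in millimetres. Voxel arrays map index `(i, j, k)` to
`origin + (c(i, j, k) - 1) * spacing`, with axial slices along the third
index. Slicer fiducial files (RAS) are converted on input by negating the
first two coordinates, and back on output; the conversion is an
involution, so round trips are exact to the printed precision.

The *vertical axis* is the patient anterior–posterior unit vector
`c(0, 1, 0)`: for a supine subject this is the gravity direction, so the
plane orthogonal to it (the patient coronal plane) is the physical
horizontal. Only two measures reference this axis — pelvic tilt and the
pelvic inlet angle β — and both therefore remain invariant under
rotations about it. Every other measure is invariant under arbitrary
rigid motion; the test suite checks both statements at `1e-9` degrees/mm.

## Seeded level tracing

A traced region is the 4-connected component, containing the seed pixel,
of pixels whose intensity differs from the seed intensity by at most a
symmetric tolerance. The literal rule "same grey level as the seed" is
the `tolerance = 0` limit; a nonzero window is what makes the rule usable
on noisy data. `suggestTolerance()` proposes half the distance between
the two Otsu intensity-class means of a slice, which on a high-contrast
bone/background slice reproduces midpoint thresholding when the seed lies
in bone.

Design choices, fixed once:

* 4-connectivity for region membership, with the region's outer boundary
  followed along pixel *cracks* (edges between pixels), yielding a closed
  simple polygon with vertices on the pixel-corner lattice. The polygon
  is oriented counter-clockwise in the (row, col) screen convention with
  the region on the left; regions touching the image border are closed
  along it.
* At a pinch corner (two diagonally adjacent region pixels whose shared
  corner also touches two background pixels) the tracer takes the
  sharpest left turn. This keeps the contour consistent with
  4-connectivity: the crack never "tunnels" through a diagonal contact.
* Processing is strictly slice-wise (axial); `segmentVolume()` unions
  per-slice regions and records seeds, tolerance and any warnings in the
  mask provenance. A traced region covering more than half its slice is
  flagged as a probable background seed, not treated as an error.

The implementation is verified against an independently written
brute-force flood-fill oracle on hundreds of random images, and obeys two
properties worth stating: the region is monotone (by set inclusion) in
the tolerance, and at `tolerance = 0` re-seeding anywhere inside a traced
region reproduces it exactly.

## Surface extraction and smoothing

The binary mask is isosurfaced at the 0.5 level by marching tetrahedra on
the Kuhn 6-tetrahedron cube decomposition. With binary node values every
edge crossing falls at the edge midpoint. Two facts make this variant
attractive for an audit-oriented pipeline: it needs no case table beyond
the 16 tetrahedron configurations, and the Kuhn split is
translation-consistent, so adjacent cubes share face diagonals and the
extracted surface is watertight and orientable by construction (the mask
is padded so the surface cannot touch the grid border). Triangles are
oriented outward using an interior reference point per tetrahedron case;
`meshVolume()` then evaluates the divergence-theorem sum of signed
tetrahedra, which is exactly translation-invariant. Accuracy on closed
forms: a 10 mm cube at 0.5 mm spacing and a 20 mm sphere at 0.8 mm
spacing are both recovered within 1%.

Smoothing is the umbrella (1-ring centroid) operator: each iteration
moves every vertex toward the mean of its neighbours by a factor λ. The
pure umbrella operator systematically shrinks closed surfaces, and on a
thin bone shell the shrinkage is material: at the default phantom
resolution (2 mm) ten iterations at λ = 0.3 remove about 2% of the
enclosed volume — over the 1% budget this pipeline treats as a hard
audit. The reference workflow this package follows smooths with a
shrink-compensating filter, and the audited quantity (volume change), not
the filter, is what is fixed; the default here is therefore the two-step
Taubin scheme, λ = 0.3 and μ = −0.31 (a ≈ 0.1 pass band), ten
iterations, which changes the phantom volume by ~0.06%. The pure
umbrella filter remains available (`mu = 0`) and its classical
properties — strict monotone shrinkage of convex meshes, vertices drawn
inside the circumscribed sphere — are what the umbrella-specific tests
exercise. `checkVolumeBudget()` computes
`100 |V_after − V_before| / V_before` and passes strictly below the
budget (default 1%).

## Landmark schema and the 21 measures

Reconstructing the full measurement suite requires 19 named points: three
on the pubic symphysis (superior/middle/inferior), five midline
sacro-coccygeal points, and five left/right pairs plus the femoral head
centres. The sacral platform centre is derivable and defaults to the
sacral promontory, in which case 18 distinct markers suffice — matching
the marker count of the source workflow under the assumption that the
promontory marker doubles as the platform point. Validation distinguishes
hard failures (missing or duplicated names) from orientation flags (e.g.
left/right sides swapped relative to the frame); measurement requires
completeness and uniqueness but tolerates re-oriented sets, since the
suite is rigid-motion invariant by design.

Measure bindings worth flagging:

* **Conjugate order.** The obstetric/true/diagonal conjugates run from
  the superior/middle/inferior symphysis points to the promontory — the
  source cohort's printed order, which differs from classical obstetric
  usage. Only this order is consistent with the published female means
  (obstetric 126.2 mm > true 122.1 mm).
* **Inlet/depth ratio.** Pelvic depth runs from the midpoint of the
  configured inlet conjugate (default obstetric) to the coccyx tip, and
  the ratio divides the same conjugate by it. With the published means
  the obstetric choice reproduces both printed ratios (1.2 female, 1.1
  male) while the true conjugate does not; the choice is configurable.
* **Reconstructed angles.** The offset angle α (at the promontory,
  between the true-conjugate line and the promontory→S3/S4 line) and the
  inlet angle β (elevation of the obstetric-conjugate line out of the
  supine horizontal plane) are reconstructions: the source names them
  without construction. Both carry reduced weight in template calibration
  and no acceptance claim depends on their absolute values.
* **Pubic tubercle height** is read as the superior–inferior symphysis
  extent, a plausible but unconfirmed interpretation (the female mean
  30.7 mm < male 34.8 mm is anatomically sensible under it).
* Angle registry entries are degrees; the published table's "(mm)" label
  on angle rows is treated as a typesetting slip.

## The synthetic generator

Only measure-level summaries (per-sex means and SDs of the 21 measures,
for 100 + 100 subjects) are published for the reference cohort — no
coordinates. The generator therefore calibrates by optimization:

1. **Template fit.** Landmark coordinates (left/right pairs mirrored
   about the mid-sagittal plane, superior symphysis pinned at the origin:
   32 free parameters) are fitted by Levenberg–Marquardt to minimize the
   weighted sum of squared *relative* measure residuals. Distances carry
   weight 1, angles and the ratio 0.25 (they are partly reconstructions).
   A negligible anchor residual (weight `1e-8` per 100 mm) toward the
   anatomical starting configuration fixes the translation gauge without
   influencing the fit. Fits are accepted only if every distance residual
   is within 5%; on the published targets the worst distance residual is
   ~0.5% for either sex, and fitting targets realized by an existing
   valid set returns to it with residuals below `1e-6` (a fixed point).
   Geometrically impossible target combinations (sacral chain triangle
   violations, a pelvic depth outside what the promontory–coccyx and
   conjugate chain permit) are rejected up front with the conflicting
   measures named.
2. **Cohort noise.** Subjects are template copies plus independent
   zero-mean isotropic Gaussian displacements per landmark. Because the
   noise projected on a measurement line contributes the sum of its
   endpoint variances, per-landmark variances are solved from the target
   SDs by non-negative least squares over the 14 distance equations
   (inlet-midpoint constituents enter with weight 1/4), then one global
   per-sex factor from a 200-draw pilot run aligns realized and target
   SDs (median ratio). Realized distance SDs land within ±25% of their
   targets; angle SDs and all between-measure correlations are emergent,
   not fitted — no covariance structure is published to fit.
3. **Bias correction.** `E|a + ε|` exceeds `|a|` by approximately
   `s²/|a|` for isotropic noise, enough to shift small-SE cohort means.
   Distance targets are therefore corrected to `m − s²/m` before the
   template fit, so that *noisy cohort means*, not template values, land
   on the published means. With this correction a 100-subject cohort
   recovers every distance-measure mean within 3 standard errors, for
   both sexes.
4. **Voxel phantom.** The bony pelvis is rasterized as a union of 8 mm
   capsules sweeping the anatomical chains of the schema (inlet ring,
   symphysis, sacrum–coccyx, pubic rami, posterior columns) plus spheres
   at every landmark (22 mm at the femoral heads), at high intensity
   against a low background — exactly the contrast property the seeded
   segmentation exploits. Rasterized volume agrees with a Monte-Carlo
   estimate of the exact solid's volume within 5% at 2 mm spacing, and
   every landmark lies inside the shell with a ≥10-voxel background
   margin.

What the phantom does *not* emulate: cortical/trabecular texture, soft
tissue, partial-volume and beam-hardening effects, or anatomical shape
variation beyond what the landmark perturbation induces. Passing the
pipeline on phantoms therefore demonstrates the correctness of the
algorithms and their calibration machinery — not segmentation robustness
on clinical scans.

## Statistics

Group comparisons use the pooled-variance Student t-test computed from
summary statistics (the published degrees of freedom, 198 at 100 + 100,
indicate the pooled test; Welch is available by flag). When both SDs are
zero the test returns p = 1 for equal means and refuses the infinite
statistic otherwise. No multiple-testing correction enters the
per-measure decisions, matching the source's 21 uncorrected tests at
p < 0.05; Bonferroni and Benjamini–Hochberg columns are appended as
supplementary output only. Published p-values were computed from
unrounded patient data, so from rounded printed summaries only
order-of-magnitude and threshold agreement is meaningful — the
obstetric-conjugate row, for instance, reproduces t ≈ 5.19 and
p ≈ 5×10⁻⁷ against a printed 4.4×10⁻⁷. One internal inconsistency of the
source is worth recording: its text claims 19 of 21 measures differed
significantly, but its own table prints three p-values above 0.05
(straight conjugate, angle χ, angle ε). `cohortTable()` reports whatever
the data give.

A-priori power uses the noncentral t distribution exactly:
`ncp = d sqrt(n1 n2 / (n1 + n2))`, critical value the central-t quantile
at `1 − α/2` with `n1 + n2 − 2` degrees of freedom, power
`P(|T| > t_crit)` under noncentrality `ncp`. At d = 0.4, α = 0.05,
n = 100/100 this reproduces the published quadruple (2.8284271,
1.9720175, 198, 0.8036475) to `1e-6`.

## Problem sizes and reproducibility

The shipped checks run at sizes a desk machine handles comfortably: the
phantom pipeline at 2 mm isotropic spacing (~1.4M voxels, ~150k mesh
faces), cohort calibration at n = 100 per sex, the flood-fill oracle on
100+ random 24–32 px slices, and the null-calibration simulation on 200
replicate cohorts of 25 + 25 drawn from one template (the p < 0.05 rate
stays within binomial 99% bounds of 0.05). Every stochastic routine takes
an explicit seed and restores the caller's RNG state; identical seeds
give bit-identical cohorts, phantoms and masks.

## Known limitations

* α and β are reconstructions; comparisons of their absolute values
  against other workflows are not meaningful.
* The oblique diameter defaults to the left sacroiliac→right eminence
  cross measure; whether the source averaged sides is unknown (a `mean`
  option exists).
* The generator's between-measure correlation structure is emergent from
  shared landmarks, not calibrated; cohort-level covariances should not
  be interpreted.
* Level tracing is strictly 2D per slice by design; no 3D region growing
  is attempted, and no model- or learning-based segmentation is offered.
* Phantoms are wireframe-like idealizations; mesh quality metrics beyond
  watertightness and volume (e.g. curvature fidelity) are out of scope.
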
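# Pelvimetry3D

Three-dimensional pelvimetry measures the bony pelvis from CT — the
inlet and outlet conjugates, the transverse, oblique and bis-ischiatic
diameters, sacral-chain distances and pelvic angles that together
describe how deep and how narrow a pelvis is. These dimensions are
strongly sex-dimorphic and directly condition the difficulty of deep
pelvic surgery (rectal resection in particular), which is why surgical
teams measure them on preoperative imaging.

Pelvimetry3D implements the full measurement workflow as a tested R
package, for image-analysis and biostatistics users who want the
pipeline reproducible end to end:

1. **Segmentation** — seeded *level tracing* on each axial slice: the
   traced region is the 4-connected set of pixels within an intensity
   tolerance of the seed, with a closed crack-boundary contour
   (`levelTrace()`, `segmentVolume()`, `suggestBoneSeeds()`).
2. **Meshing** — marching-tetrahedra isosurfacing of the binary mask at
   the 0.5 level into a watertight triangle mesh, Laplacian (umbrella)
   smoothing with a shrink-compensating default, and a hard audit that
   smoothing changed the enclosed volume by less than 1%
   (`extractSurface()`, `laplacianSmooth()`, `meshVolume()`,
   `checkVolumeBudget()`).
3. **Pelvimetry** — 21 scalar measures per subject from a 19-landmark
   fiducial schema, with Slicer-compatible landmark I/O
   (`computePelvimetry()`, `measureRegistry()`, `readLandmarks()`).
4. **Statistics** — sex-stratified cohort tables with pooled two-sample
   t-tests computed from summaries, and exact a-priori power analysis
   under the noncentral t distribution (`cohortTable()`, `twoSampleT()`,
   `tPower()`).
5. **Synthetic cohorts** — because clinical CTs of this kind are not
   publicly deposited, a generator fits sex-specific landmark templates
   to published per-measure means/SDs by Levenberg–Marquardt, samples
   calibrated Gaussian landmark noise, and rasterizes bone-like voxel
   phantoms so every stage above is testable without patient data
   (`buildTemplate()`, `sampleLandmarkCohort()`, `rasterizePhantom()`).

The statistical core in standard notation: for two groups with summary
statistics (n₁, m₁, s₁) and (n₂, m₂, s₂),

    s_p² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁+n₂−2),
    t    = (m₁ − m₂) / (s_p √(1/n₁ + 1/n₂)),  df = n₁+n₂−2,

and a-priori power for effect size d uses the noncentral t with
noncentrality δ = d √(n₁n₂/(n₁+n₂)) and two-sided critical value
t₍1−α/2, df₎: power = P(|T| > t_crit | δ).

## Worked example

Reproduce the a-priori power computation for two groups of 100:

```r
library(Pelvimetry3D)
tPower(d = 0.4, n1 = 100, n2 = 100, alpha = 0.05)
#> Two-sample t-test a-priori power (two-tailed)
#>   d = 0.4, alpha = 0.05, n = 100/100
#>   noncentrality = 2.8284271
#>   critical t    = 1.9720175
#>   df            = 198
#>   power         = 0.8036475
```

Fit a female template to published targets and measure it:

```r
fit <- buildTemplate(defaultMeasureTargets("female"))
rec <- computePelvimetry(fit$landmarks)
round(measures(rec)[c("obstetric_conjugate", "pelvic_depth",
                      "inlet_depth_ratio")], 2)
#> obstetric_conjugate        pelvic_depth   inlet_depth_ratio
#>              125.69              103.25                1.22
```

The obstetric conjugate lands within 0.5% of its 126.2 mm target, the
pelvic depth near 102.8 mm, and their ratio prints 1.2 at one decimal —
the published female value. Simulate two 100-subject cohorts and compare
them measure by measure:

```r
f <- sampleLandmarkCohort(phantomParams("female", seed = 7), 100)
m <- sampleLandmarkCohort(phantomParams("male",   seed = 8), 100)
recs <- c(lapply(f, computePelvimetry), lapply(m, computePelvimetry))
tab <- cohortTable(recs, rep(c("female", "male"), each = 100))
tab[tab$measure %in% c("obstetric_conjugate", "bis_ischiatic_diameter",
                       "pelvic_depth"),
    c("measure", "mean1", "sd1", "mean2", "sd2", "t", "p")]
#>                 measure   mean1     sd1   mean2    sd2      t         p
#>     obstetric_conjugate 124.495  8.4909 119.061 9.4839  4.269 3.045e-05
#>  bis_ischiatic_diameter 116.095 11.3533 102.580 7.8313  9.799 9.810e-19
#>            pelvic_depth 102.453  9.6296 111.882 9.1802 -7.087 2.353e-11
```

Female pelves come out wider (larger inlet and bis-ischiatic diameters)
and shallower (smaller pelvic depth), each difference far below the 0.05
level — the dimorphism pattern the measurement suite is built to detect.
A t-test straight from printed summary statistics works too:

```r
twoSampleT(groupSummary("pelvic_depth", 100, 102.8, 9.8, 100, 111.5, 8.8))
#> t = -6.6053, df = 198, two-tailed p = 3.575e-10 (mean diff -8.7)
```

The full imaging chain, from phantom to audited smoothed mesh:

```r
res <- phantomSmoothingAudit("female", spacing = 2, seed = 1)
res$audit$realized_percent   # 0.061 — well under the 1% budget
```

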
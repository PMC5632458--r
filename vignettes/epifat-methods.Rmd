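---
title: "Epicardial fat segmentation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epicardial fat segmentation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifat)
```

## The problem

Epicardial adipose tissue — the visceral fat between the myocardium and the
pericardium — is a clinically useful marker of cardiovascular risk, and its
volume is measured from contrast cardiac CT. Manual delineation is slow and
poorly reproducible, while fully automatic methods struggle because
epicardial fat, paracardial (mediastinal) fat and other low-attenuation
tissue are indistinguishable by intensity alone. `epifat` implements a
semiautomatic middle ground: the user marks a single patch of epicardial
fat and supplies a handful of per-slice arc angles; everything else is
automatic.

## The pipeline

Each slice `X` (12-bit, `M x N`) passes through five stages. Coordinates
are 1-based `(row, col)`, with the row index playing the role of the x-axis.

**1. Tone mapping.** A histogram-adaptive contrast stretch: values are
clipped at the 1st/99th percentiles and rescaled linearly to `[0, 1]`. The
mapping is monotone, so tissue ordering is preserved; the percentile form
makes it adaptive to each acquisition without introducing the
histogram-warping of equalization.

**2. Whole-heart ROI.** Grayscale opening by reconstruction with a disk of
diameter `ms1 = 40` px removes bright structures narrower than the disk
(rib sections, sternum fragments) while leaving the heart's shape exactly
intact; Otsu's threshold on the reconstruction separates soft tissue from
the dark lung fields; the largest connected component keeps the heart and
its mediastinal surround and drops disconnected bright debris; a final
dilation by a disk of diameter `ms2 = 20` px pads the region so the fat rim
on the heart surface is inside the mask. The reconstruction is the exact
fixed point of the 8-connected unit geodesic dilation, computed by the
standard hybrid raster/queue algorithm in compiled code and verified in the
tests against a literal unit-step iteration.

**3. Seeded fuzzy clustering.** `R x R` patches (`R = 5`, stride 2) are
sampled inside the ROI; each contributes the feature `u = (u1, u2)` — patch
mean and biased patch variance of the enhanced luminance. Features are
z-scored over the patch set (mean and variance live on different scales)
and clustered by fuzzy c-means (`C = 6`, fuzzifier `m = 2`, tolerance
`1e-5`, deterministic seeded initialization with 3 restarts keeping the
lowest objective). The user's reference patch is mapped through the same
z-transform, and the cluster whose membership-weighted mean feature is
closest to it (squared Euclidean distance) is selected as the fat cluster.
Patch memberships are then projected to pixels: each pixel's membership is
the mean over all patches covering it, zero outside the ROI.

**4. Referent ellipse.** The selected soft cluster is summarized by an
ellipse: center from luminance-and-membership-weighted first moments;
orientation from PCA of the membership-weighted point cloud (covariance
regularized by diagonal loading `1e-6 * trace / 2`); and axes `(a, b)` from
a bounded least-squares fit in the rotated, centered frame,

    minimize  sum_ij X(i,j) mu(i,j) [ (a cos phi_ij - x~)^2 + (b sin phi_ij - y~)^2 ]
    subject to  B_l < a, b < B_u,

solved with L-BFGS-B from the deterministic second-moment start. The
per-point angle `phi_ij = atan2(y~/b, x~/a)` is the parameter angle
consistent with the candidate axes, so the objective vanishes exactly on
noise-free elliptical data and the bounds `(200, 450)` px only need to
bracket plausible cardiac silhouettes on a 512-wide grid.

**5. Arc/ring filtering.** The fuzzy field is defuzzified by an inclusive
α-cut (`alpha = 0.7`); a pixel of the crisp set survives only if its polar
angle in the ellipse frame lies within the per-slice arc `[phi1, phi2]`
(linearly interpolated from control slices) and its radial distance to the
ellipse, `| sqrt(x~^2+y~^2) - ab / sqrt(b^2 cos^2 phi + a^2 sin^2 phi) |`,
is at most `epsilon = 20` px. A morphological closing (disk `ms2`) smooths
the result. This is where epicardial fat is separated from paracardial fat
and other fat-like tissue: both predicates are geometric, not
intensity-based.

All pixel-dimensioned defaults — `ms1`, `ms2`, `epsilon`, the closure
diameter and the bounds — presume a 512-wide grid and are rescaled by
`image_width / 512` at run time (`scale_to_grid`).

## Control angles are trained, not geometric

The arc predicate operates in the *fitted* ellipse frame. On a
near-circular fat rind with an angular gap, the principal direction of the
cluster cloud is governed by the gap position rather than by the slight
eccentricity of the heart (removing mass at one axis end flips the
principal axis towards the perpendicular). The fitted orientation is
therefore a stable property of the data but not an estimate of the
anatomical major axis — and arc angles defined in anatomical coordinates
would land in the wrong sector. The operational protocol mirrors this: the
control angles are set on training data *through the pipeline* (an expert
marks where fat appears relative to the fitted ellipse), and
`calibrate_control_angles()` implements exactly that — it maps reference
fat pixels of a training run into the fitted frame and returns the
complement of the largest empty angular gap. The frame bias is absorbed
into the trained angles, which is also why the whole construction is
rotation-consistent (tested: rotating the phantom rotates the fitted frame
and leaves the Dice unchanged within 0.02).

## Choices where the formulation was open

* **Pondered cluster mean.** Dividing the membership-weighted feature sum
  by the number of patches `Q` (rather than by the membership sum) shrinks
  every cluster mean towards the z-score origin by its mass fraction, so
  the seed-matching distance compares cluster *sizes* instead of
  *locations*; on the phantom it never selects the fat cluster. The
  package defaults to the conventional weighted mean
  (`pondered_mean = "normalized"`) and keeps the alternative as a config
  switch.
* **Orientation observation model.** Building the cloud as
  `mu * [i, j]` collapses the many low-membership ROI pixels towards the
  coordinate origin; the covariance is then dominated by the
  origin-to-centroid separation and the estimated angle locks onto the
  image diagonal (~45° on a centered grid) regardless of the cluster's
  shape. The default is the weighted-average model (`mu` as statistical
  weights); the coordinate-scaling form is available as
  `orientation_mode = "weighted_coords"`.
* **Number of clusters.** `C` is an empirical, acquisition-dependent
  parameter. On the phantom's tissue classes the global c-means optimum at
  `C = 5` merges fat with myocardium/mediastinum (restarts make this
  *worse*, because the merged solution has the lower objective); `C = 6`
  separates fat on every seed — one cluster each for fat, bright blood and
  bone, lung remnants, myocardium plus mediastinal soft tissue, and two
  transitional-texture groups. `C = 6` is the default.
* **Radial forms.** The ring distance uses the true polar radius and the
  ellipse's polar radius at the point's angle; the literal squared forms
  (which are dimensionally inconsistent with a pixel distance) are
  reproducible via `distance_mode = "as_printed"`. The ring test is
  two-sided (`|rho - rho_RE| <= epsilon`).
* **Numerical details.** Inclusive comparisons at `mu = alpha` and
  `d = epsilon`; ties in cluster selection break to the lowest index; a
  point at the ellipse center (undefined angle) is assigned distance
  `min(a, b)`; degenerate orientation clouds are regularized by the
  diagonal loading and flagged unreliable; structuring elements are disks
  whose "size" is the diameter in pixels, rounded up to odd; per-slice
  failures (constant slice, empty ROI, empty cluster) emit a warning and
  an empty mask so volume runs never abort.

## The phantom

`phantom_spec()` renders a 512 x 512, 12-bit synthetic slice with the
tissue geometry the pipeline has to cope with: a rotated elliptical heart
(semi-axes 216 x 200 px, orientation 20°) with a contrast-filled blood pool
and papillary-muscle texture; a 16 px (≈ 5.6 mm at 0.35 mm/px) epicardial
fat rind over the arc 15°–345° (a near-circumferential rind with a
posterior gap); a 2 px pericardial line; *paracardial* fat patches of
identical luminance outside the pericardium — the confound the geometric
prior exists to reject; mediastinal soft tissue; dark lung fields; a
vertebral body and isolated rib sections as bright bone distractors.
Luminances are approximately shifted Hounsfield units (HU + 1024: lung 200,
fat 950, mediastinum 1040, myocardium 1070, pericardium 1100, blood 1320,
bone 1700) — an ordering claim, not a calibration claim — and the default
additive noise s.d. is 25, typical of CT. Geometry can drift linearly
across slices to exercise control-angle interpolation, and every run is
bit-reproducible from its seed.

What the phantom does *not* emulate: partial-volume blur, beam-hardening
and streak artifacts, anatomical shape variability, or fat inside the
atrioventricular grooves. Passing the phantom therefore demonstrates the
pipeline's internal consistency and its robustness to intensity overlap
and geometric confounds, not clinical-grade accuracy.

## What to expect quantitatively

On ten default-noise phantoms (controls trained on a held-out training
phantom, everything else at the shipped defaults) the median Dice against
ground truth is just above 0.8, with median volume error around 5% —
computed live by `scripts/acceptance.R` and the acceptance tests. Two
structural error sources bound this from above, and they do not vanish at
zero noise: (i) the α-cut of patch-mean memberships erodes one to two
pixels at each rind boundary, because boundary patches are tissue mixtures
whose fat membership hovers near 0.5; (ii) pericardial-interface and
paracardial pixels within the ε-ring survive the geometric filter. At zero
noise the Dice is essentially unchanged (≈ 0.81), which is why we report
the noise sweep as a robustness check rather than expecting convergence to
a perfect segmentation; a near-1 Dice would require a fat rind several
times thicker than anatomy provides at this resolution.

The noise response is, notably, *not* monotone: moderate noise (s.d. ~100)
slightly raises the Dice, because noise dithers boundary-patch memberships
and lifts part of the eroded rind boundary back above the α-cut, while
heavy noise (s.d. ≳ 200) collapses the mean/variance texture clusters and
the segmentation with them. The tests assert the two ends of this curve
(mild noise harmless, heavy noise destructive) rather than a monotone
middle that the method does not exhibit.

Problem sizes used throughout the tests and the acceptance script — a
single 512 x 512 slice per run, ten noise seeds, 10^4-point orientation
clouds, 5000-sample clustering contracts — are the package's validation
choices; they keep every property measurable in seconds while exercising
the full-resolution geometry.

## Limitations

The method is 2D per slice (no volumetric regularization beyond linearly
interpolated control angles); it needs one seed patch per patient and
trained control angles per acquisition protocol; the center-of-gravity
estimate is biased away from the arc gap, which the ε-ring must absorb;
and the fitted orientation is meaningful only relative to the training
protocol, as discussed above. None of the clinical correlations that
motivate epicardial fat quantification are computable from the phantom.
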
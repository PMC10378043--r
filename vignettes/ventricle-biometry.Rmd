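---
title: "Automated linear biometry of the fetal lateral ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated linear biometry of the fetal lateral ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventrimetry)
```

## The measurement problem

Fetal ventriculomegaly (VM) — dilatation of the lateral cerebral ventricle —
is the most common CNS malformation seen in prenatal imaging. The clinical
criterion is linear, not volumetric: an atrial width greater than 10 mm,
measured perpendicular to the ventricle's long axis on an axial plane through
the thalamus, at the posterior margin of the glomus of the choroid plexus.
Dilatation is graded mild (10–12 mm), moderate (13–15 mm) or severe
(> 15 mm), and a left–right asymmetry of up to 2.4 mm without dilatation is a
normal variant.

`ventrimetry` automates this 2D measurement from a 3D seven-tissue
segmentation of a reconstructed fetal-brain MR volume (external CSF, grey
matter, white matter, ventricles, cerebellum, deep grey matter, brainstem —
the FeTA convention). Producing that segmentation (brain extraction,
super-resolution reconstruction, the segmentation network itself) is
upstream of this package: the label volume is an *input*, with a documented
contract, not something the package computes.

## The procedure

Given a co-registered intensity volume $I$ and label volume $L$ at (nominally)
0.5 mm isotropic spacing:

1. **Reference slice.** For each axial slice $k$ (axial is defined by the
   volume's anatomical orientation code, not by array order), compute the
   deep-grey-matter area $A_k = \#\{(i,j): L_{ijk} = \mathrm{DGM}\}\cdot
   s_x s_y$. The reference slice is $\arg\max_k A_k$; the thalamus belongs
   to the DGM class, so this approximates the clinical thalamic plane. Ties
   break to the smallest (most inferior) index, and the profile is not
   smoothed — the procedure is a plain maximum.
2. **Components.** On the reference slice, label the ventricle class with
   8-connected component analysis. Typical slices produce three components:
   the left ventricle, the right ventricle and the cavum septum pellucidum
   (CSP), which also carries the ventricle label. Components smaller than
   4 px are discarded as speckle. The two largest components are the lateral
   ventricles; the one whose centroid lies on the subject-left side of the
   midline (per the orientation code) is *left*; a third component lying
   between the two along the left–right axis is the CSP.
3. **Refinement.** For each ventricle component, compute the mean intensity
   $m$ over its pixels and keep exactly the pixels with
   $I_{ij} \ge m$ (the comparison is `>=`, so a perfectly uniform component
   is kept whole). CSF is the brightest tissue on T2-weighted images, so
   this removes both the dark partial-volume fringe of the segmentation and
   the choroid plexus glomus, which is always dark. Only the largest
   8-connected piece of the thresholded mask is retained; if thresholding
   empties the mask entirely the original component is used and no plexus is
   reported.
4. **Width.** Fit the minimum-area rotated rectangle to the refined mask
   (rotating calipers over the convex hull of the pixel centres). Side
   lengths are converted to mm and augmented by one pixel pitch, so a solid
   axis-aligned run of $n$ pixels measures $n \cdot s$ mm. Reorienting the
   segment so the rectangle's long side is horizontal, the atrial width is
   the vertical extent — the rectangle's short side. This is the default
   `minrect` mode.

Each step names itself in its error messages, so a failed case reports which
stage broke and why.

### The `plexus_margin` mode

Clinically the calipers are placed at the *posterior margin of the glomus*,
not necessarily at the widest point. The published description of this
adjustment ("the line is moved from the largest diameter towards the choroid
plexus") has no stopping rule, so this package formalises it explicitly as an
opt-in mode: after reorientation, the removed-pixel cluster nearest the
posterior end (posterior comes from the orientation code) is taken as the
glomus; at the horizontal station of that cluster's margin closest to the
component centroid, the width is the vertical extent of the refined mask in
that pixel column. When binarization removed no plexus-sized cluster the mode
falls back to `minrect`. `auto` selects `plexus_margin` exactly when a plexus
was detected. `minrect` remains the default because it is fully deterministic
and assumption-free; neither mode claims to replicate unpublished code.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| VM threshold | 10.0 | mm | case is ventriculomegaly iff either width strictly exceeds it |
| severity edges | 10, 13, 15 | mm | normal ≤ 10 < mild < 13 ≤ moderate ≤ 15 < severe |
| asymmetry allowance | 2.4 | mm | flag for normal cases only ("without dilatation") |
| agreement threshold ε | 1.7 | mm | strict \|a−b\| < ε counts as agreement |
| component area floor | 4 | px | suppress segmentation speckle |
| in-plane isotropy tolerance | 1 | % | a scalar mm width is ill-defined on anisotropic pixels; violation is an error |

All pipeline thresholds live in a single `RunConfig` object; there are no
hidden constants. Two boundary choices deserve a note, because the published
prose is ambiguous: exactly 10.0 mm is *normal* (the criterion is strictly
"wider than 10 mm"), and the integer grade ranges 10–12 / 13–15 leave the
interval (12, 13) unassigned — here mild extends up to 13 mm. Both are
configurable.

## The synthetic phantom

Real fetal MR volumes cannot ship with a package, so every downstream stage
is validated against `makePhantom()`, which emits a label volume, an
intensity volume and the exact ground truth:

* an ellipsoidal white-matter brain with a cortical grey-matter shell;
* two ventricle-labelled elliptic cylinders, centred 13 mm either side of
  the midline, major axis along anterior–posterior, rotated in-plane by a
  configurable angle (mirrored between sides). The requested width is
  snapped to a whole number of in-plane voxels and the centre is placed on a
  voxel centre (odd count) or voxel boundary (even count), so at zero
  rotation the rasterized minor diameter is *exact*; the truth object
  reports the snapped width;
* a deep-grey-matter blob built from per-slice discs following an
  ellipsoidal radius profile, with the disc at the requested reference slice
  enlarged by 0.6 voxel so its rasterized area is strictly maximal (a plain
  ellipsoid can tie between neighbouring slices after rasterization);
* optionally a midline CSP component (ventricle label) and, in the
  posterior third of each ventricle, a dark glomus whose intensity (40) is
  at most half the within-ventricle mean, so the mean-intensity threshold
  provably excludes it. The glomus's inner margin sits one third of the
  major semi-axis behind the centre;
* intensities 200 (CSF/ventricles), 100 (parenchyma), plus additive Gaussian
  noise (sd 2 by default) clipped at zero, reproducible from a seed.

The defaults (128×128×64 voxels at 0.5 mm, ventricle length 20 mm, widths
8 mm) were chosen once as representative of a mid-gestation
super-resolution-reconstructed volume.

What the phantom does **not** emulate: cortical folding, motion artifacts,
bias fields, partial-volume fringes with realistic intensity profiles,
asymmetric frontal/occipital horn anatomy, or segmentation errors of a real
network. Passing the phantom suite therefore demonstrates the geometry of the
measurement — slice selection, laterality, plexus exclusion, rectangle
fitting — not performance on clinical data, which additionally depends on the
upstream segmentation quality.

## Numerical choices

* **Connectivity** is 8-connected in 2D, on the reference slice only;
  corner-touching regions merge.
* **Rectangle augmentation.** Side lengths are pixel-centre extents plus one
  pitch. The minimum of this *augmented* area need not occur exactly at a
  convex-hull edge direction (the classical theorem applies to the
  unaugmented area), so the calipers sweep over edge directions is refined by
  1-D optimisation within each angular interval. On 200 random point sets
  the result stays within 0.5 % of a 0.1°-stepped brute-force minimum.
* **Ties** break deterministically everywhere: smallest slice index for the
  reference slice, first-found component for equal-size largest pieces,
  series id for equal segmented volumes.
* **Degenerate masks** (collinear pixel centres) get a rectangle whose short
  side is one pixel pitch; an empty refined mask falls back to the
  unrefined component.
* **Laterality** follows the NIfTI convention: each orientation letter names
  the anatomical direction of increasing array index, and subject-left is
  resolved from the left–right axis letter. Volumes without a valid
  qform/sform are assumed RAS with a warning.
* **Display rounding** is half-up at two decimals; all internal comparisons
  use full precision.

## Known inconsistencies in the published comparison tables

The bundled 22-case table reproduces the published per-case widths exactly,
and the package recomputes all summary statistics from them. Four published
summaries are *not* reproducible from the published per-case values
themselves, and are asserted as discrepancies by the test suite rather than
used as references:

* the paired-t p-values (printed 0.9827, 0.2378, 0.0043) recompute to
  0.9479, 0.2733 and 0.0527 under a standard two-sided paired t over the 44
  pooled ventricles;
* one SD cell (general radiologist, right, normal cases) prints 1.29 but
  recomputes to 1.2991, i.e. 1.30 at two decimals;
* the abnormal-case summary means printed for the automated rater (11.22 /
  10.79 mm) disagree with the mean of their own column values (12.75 /
  12.25 mm); the fixture keeps the per-case values and recomputes summaries;
* the abstract quotes 0.82 mm for the neuroradiologist-vs-automated pooled
  error where the comparison table and conclusions give 0.84 mm; the fixture
  reproduces 0.84.

One further caveat: case-level reference labels come from radiology reports,
not from the 10 mm rule applied to the table (one case is grouped abnormal
although the neuroradiologist read both sides under 10 mm). This package
classifies from widths only. The published left-ventricle R² values
(0.93, 0.92) appear to be truncated rather than rounded (they recompute to
0.9354 and 0.9231, while the right-ventricle values are printed to nine
decimals and match exactly).

## Problem sizes and determinism

The test suite and the acceptance script regenerate every fixture in code:
16 phantoms (widths 6, 9, 12, 16 mm × rotations 0, 15, 30, 60°) for
parameter recovery, 200 random ≤ 30-point sets for the rectangle oracle, and
the bundled 22-case table for the agreement statistics. These sizes keep a
full run in well under a minute while giving the recovery statistics a
32-measurement sample. All randomness is seeded; identical spec + seed
yields bit-identical phantoms.

## A worked example

```{r example, eval = FALSE}
ph <- makePhantom(phantomSpec(rightWidthMm = 12, leftWidthMm = 8,
                              rotationDeg = 30))
m <- measureCase(ph$intensity, ph$labels)
m$right
#> right ventricle: 12.13 mm (minrect, slice 32, plexus detected)
classifyCase(m$right@widthMm, m$left@widthMm)
#> Case: ventriculomegaly (right 12.13 mm [mild], left 8.30 mm [normal],
#>   asymmetry 3.82 mm)

buildAgreementReport(readMeasurementTable(bundledMeasurementTable()))
```

## Limitations

* The package measures; it does not segment. Errors in the upstream tissue
  segmentation propagate directly into the width.
* A single scalar width per ventricle assumes isotropic in-plane pixels;
  anisotropic slices are rejected rather than silently averaged.
* The atrium is identified implicitly (largest components, plexus position);
  grossly abnormal anatomy (e.g. fused ventricles crossing the midline)
  triggers warnings and relative-position fallbacks rather than a guaranteed
  correct laterality.
* 3D ventricular volumetry, other biometrics (pons, vermis, biparietal
  diameters) and DICOM ingestion are out of scope.
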
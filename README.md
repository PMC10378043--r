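# ventrimetry

Automated 2D linear measurement of the fetal lateral ventricle from a
segmented 3D fetal-brain MR volume, with ventriculomegaly classification and
rater-agreement statistics.

## The problem

Fetal ventriculomegaly — dilatation of the lateral cerebral ventricle — is
diagnosed from a *linear* measurement: the atrial width, taken on an axial
plane through the thalamus, perpendicular to the ventricle's long axis, at
the posterior margin of the glomus of the choroid plexus. Width > 10 mm is
abnormal; 10–12 mm mild, 13–15 mm moderate, > 15 mm severe. Manual
measurement requires picking the right slice out of many series and placing
calipers consistently; this package automates the measurement for anyone who
already has a seven-tissue segmentation of a reconstructed fetal brain
volume (FeTA-style labels: external CSF, grey matter, white matter,
ventricles, cerebellum, deep grey matter, brainstem).

## The method

Given co-registered intensity and label volumes (NIfTI):

1. **Reference slice** — the axial slice maximizing the deep-grey-matter
   area `A_k = #{L_ijk = DGM} · s_x s_y` (the thalamus is part of DGM, so
   this approximates the clinical thalamic plane).
2. **Components** — 8-connected labeling of the ventricle class on that
   slice separates left ventricle, right ventricle and cavum septum
   pellucidum; laterality comes from the volume's anatomical orientation
   code.
3. **Refinement** — binarize each component at its mean intensity
   (`I_ij ≥ m` is kept), removing the dark segmentation fringe and the
   choroid plexus glomus; keep the largest connected piece.
4. **Width** — the short side of the minimum-area rotated rectangle
   (rotating calipers over the convex hull of pixel centres, side lengths
   augmented by one pixel pitch): the extent perpendicular to the
   ventricle's long axis, in mm.

Widths are then graded and the case is classified (ventriculomegaly iff
either side > 10 mm; asymmetry > 2.4 mm flagged on normal cases). An
agreement module computes mean absolute differences, squared Pearson
correlations, paired t-tests and threshold-agreement counts between raters,
and the package bundles a published 22-case comparison table (general
radiologist, neuroradiologist, automated) as `tables_2_3.csv`.

A synthetic phantom generator (`makePhantom`) builds label + intensity
volumes with exactly known ventricle widths, reference slice, plexus
positions and component counts, so the whole chain is testable without
clinical data.

## Worked example

```r
library(ventrimetry)

ph <- makePhantom(phantomSpec(rightWidthMm = 12, leftWidthMm = 8,
                              rotationDeg = 30))
m <- measureCase(ph$intensity, ph$labels)
m$slice
#> ReferenceSlice 32 (DGM area 125.00 mm^2 over 64 slices)
m$right
#> right ventricle: 12.13 mm (minrect, slice 32, plexus detected)
m$left
#> left ventricle: 8.30 mm (minrect, slice 32, plexus detected)

classifyCase(m$right@widthMm, m$left@widthMm)
#> Case: ventriculomegaly (right 12.13 mm [mild], left 8.30 mm [normal],
#>   asymmetry 3.82 mm)
```

The phantom asked for 12 and 8 mm; the automated measurement recovers
12.13 and 8.30 mm from the rasterized, noisy volume and classifies the case
as mild ventriculomegaly on the right.

Agreement statistics on the bundled comparison table:

```r
tab <- readMeasurementTable(bundledMeasurementTable())
buildAgreementReport(tab)
#> AgreementReport: 3 pair(s), epsilon 1.70 mm
#>   rater_a rater_b mad_right_mm mad_left_mm mad_pooled_mm r2_right r2_left
#> 1     gen   neuro       0.5455      0.4818        0.5136   0.9800  0.9850
#> 2     gen      ai       0.7727      1.0318        0.9023   0.9482  0.9354
#> 3   neuro      ai       0.5364      1.1409        0.8386   0.9649  0.9231
```

The two radiologists differ by 0.51 mm on average over the 44 ventricles;
the automated measurements sit 0.90 mm from the general radiologist and
0.84 mm from the neuroradiologist, with right-ventricle R² of 0.948 and
0.965.

A thin command line wraps the same functions
(`inst/exec/ventrimetry`): subcommands `phantom`, `measure`, `classify`,
`agree`, `pipeline`; exit codes 0/1/2 for ok / input error / internal error.

```sh
Rscript inst/exec/ventrimetry classify --right 11.2 --left 9.0
```

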
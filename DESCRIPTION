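Package: ventrimetry
Title: Automated Linear Measurement of the Fetal Lateral Ventricle from
    Segmented Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures the atrial width of the fetal lateral ventricles from a
    seven-tissue segmentation of a reconstructed 3D fetal-brain MR volume. The
    axial reference slice is chosen by maximal deep-grey-matter area, the
    ventricle label is split into left/right/septal components by 8-connected
    labeling, a mean-intensity binarization removes the choroid plexus and
    segmentation fringe, and each ventricle's width is read off the short side
    of its minimum-area enclosing rectangle (rotating calipers over the convex
    hull). Widths are graded into normal/mild/moderate/severe ventriculomegaly
    with an asymmetry flag. A synthetic phantom generator provides label and
    intensity volumes with known ground-truth widths, and an agreement module
    computes rater-vs-rater statistics (mean absolute difference, R-squared,
    paired t, threshold agreement) on bundled or user measurement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'io.R'
    'phantom.R'
    'sliceSelect.R'
    'components.R'
    'binarize.R'
    'minAreaRect.R'
    'measure.R'
    'classify.R'
    'agreement.R'
    'pipeline.R'
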
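#' @import methods
NULL

## ---------------------------------------------------------------------------
## Volumes
## ---------------------------------------------------------------------------

#' 3D intensity volume with voxel geometry
#'
#' Holds a reconstructed scalar MR volume together with its voxel spacing and
#' a three-letter anatomical orientation code. The code letter for each array
#' axis names the anatomical direction of *increasing* index, following the
#' NIfTI convention: \code{R}/\code{L} = subject right/left, \code{A}/\code{P}
#' = anterior/posterior, \code{S}/\code{I} = superior/inferior. \code{"RAS"}
#' therefore means axis 1 runs to the subject's right, axis 2 anterior and
#' axis 3 superior.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing Numeric length-3, mm per voxel along each array axis.
#' @slot orientation Three-letter axis code, e.g. \code{"RAS"}.
#' @export
setClass("VolumeGrid",
    representation(data = "array", spacing = "numeric", orientation = "character"),
    prototype(spacing = c(0.5, 0.5, 0.5), orientation = "RAS"))

setValidity("VolumeGrid", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must have exactly 3 axes")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive numbers")
    ori <- tryCatch(.axisInfo(object@orientation), error = function(e) e)
    if (inherits(ori, "error")) msg <- c(msg, conditionMessage(ori))
    if (length(msg)) msg else TRUE
})

#' 3D integer tissue label map
#'
#' The main input of the measurement workflow: a seven-class fetal brain
#' tissue segmentation co-registered with its intensity volume. The default
#' label scheme follows the FeTA convention (see \code{\link{fetaLabelScheme}}):
#' 0 background, 1 external CSF, 2 grey matter, 3 white matter, 4 ventricles,
#' 5 cerebellum, 6 deep grey matter, 7 brainstem.
#'
#' @slot labels 3D integer array.
#' @slot spacing,orientation As in \code{\linkS4class{VolumeGrid}}.
#' @slot labelScheme Named integer vector mapping tissue names to codes.
#' @export
setClass("LabelVolume",
    representation(labels = "array", spacing = "numeric",
                   orientation = "character", labelScheme = "integer"),
    prototype(spacing = c(0.5, 0.5, 0.5), orientation = "RAS"))

setValidity("LabelVolume", function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "labels must have exactly 3 axes")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive numbers")
    ori <- tryCatch(.axisInfo(object@orientation), error = function(e) e)
    if (inherits(ori, "error")) msg <- c(msg, conditionMessage(ori))
    if (is.null(names(object@labelScheme)) || anyDuplicated(object@labelScheme))
        msg <- c(msg, "labelScheme must be a named integer vector with unique codes")
    bad <- setdiff(unique(as.vector(object@labels)), object@labelScheme)
    if (length(bad))
        msg <- c(msg, sprintf("label value(s) outside the scheme: %s",
                              paste(sort(bad), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' One acquired series and its segmentation
#'
#' @slot seriesId Character identifier (used as the ranking tie-break).
#' @slot labelVolume The series' \code{\linkS4class{LabelVolume}}.
#' @slot plane One of \code{"axial"}, \code{"coronal"}, \code{"sagittal"}.
#' @export
setClass("SeriesStack",
    representation(seriesId = "character", labelVolume = "LabelVolume",
                   plane = "character"))

setValidity("SeriesStack", function(object) {
    if (!object@plane %in% c("axial", "coronal", "sagittal"))
        return("plane must be one of axial/coronal/sagittal")
    TRUE
})

## ---------------------------------------------------------------------------
## Planar geometry
## ---------------------------------------------------------------------------

#' 2D boolean region on an axial slice
#'
#' @slot mask Logical matrix, full slice size (TRUE = region pixel).
#' @slot spacing Numeric length-2, mm per pixel along (rows, cols).
#' @slot sliceIndex 0-based index of the slice along the superior--inferior
#'   axis of the parent volume.
#' @slot axes Integer length-2: which volume array axes the mask rows and
#'   columns correspond to (in ascending order for slices cut from a volume).
#' @export
setClass("PlanarMask",
    representation(mask = "matrix", spacing = "numeric",
                   sliceIndex = "integer", axes = "integer"),
    prototype(sliceIndex = 0L, axes = c(1L, 2L)))

setValidity("PlanarMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 2 positive numbers")
    if (length(object@axes) != 2L) msg <- c(msg, "axes must have length 2")
    if (length(msg)) msg else TRUE
})

#' Minimum-area enclosing rectangle
#'
#' Side lengths are in mm and include one pixel pitch beyond the pixel-centre
#' extent, so a solid axis-aligned run of n pixels at pitch p has side n*p.
#'
#' @slot center Numeric length-2 (row, col), 1-based pixel coordinates.
#' @slot longSideMm,shortSideMm Side lengths, long >= short > 0.
#' @slot angleDeg Orientation of the long side in degrees within [-90, 90),
#'   measured from the column (x) direction towards the row (y) direction.
#' @export
setClass("RotatedRect",
    representation(center = "numeric", longSideMm = "numeric",
                   shortSideMm = "numeric", angleDeg = "numeric"))

setValidity("RotatedRect", function(object) {
    msg <- character()
    if (length(object@center) != 2L) msg <- c(msg, "center must have length 2")
    if (object@shortSideMm <= 0 || object@longSideMm < object@shortSideMm)
        msg <- c(msg, "need longSideMm >= shortSideMm > 0")
    if (object@angleDeg < -90 || object@angleDeg >= 90)
        msg <- c(msg, "angleDeg must lie in [-90, 90)")
    if (length(msg)) msg else TRUE
})

#' One ventricle's width measurement with provenance
#'
#' @slot side \code{"left"} or \code{"right"}.
#' @slot widthMm Measured atrial width in mm.
#' @slot method \code{"minrect"} (short side of the minimum-area rectangle)
#'   or \code{"plexus_margin"} (vertical extent at the choroid-plexus margin).
#' @slot sliceIndex 0-based reference slice index.
#' @slot plexusDetected Whether binarization removed a plexus-sized cluster.
#' @slot rect The \code{\linkS4class{RotatedRect}} of the refined segment.
#' @slot thresholdUsed The mean-intensity binarization threshold.
#' @export
setClass("VentricleMeasurement",
    representation(side = "character", widthMm = "numeric", method = "character",
                   sliceIndex = "integer", plexusDetected = "logical",
                   rect = "RotatedRect", thresholdUsed = "numeric"))

setValidity("VentricleMeasurement", function(object) {
    msg <- character()
    if (!object@side %in% c("left", "right"))
        msg <- c(msg, "side must be left or right")
    if (!object@method %in% c("minrect", "plexus_margin"))
        msg <- c(msg, "method must be minrect or plexus_margin")
    if (object@widthMm <= 0) msg <- c(msg, "widthMm must be positive")
    if (object@widthMm > object@rect@longSideMm + 1e-9)
        msg <- c(msg, "widthMm cannot exceed the rectangle long side")
    if (length(msg)) msg else TRUE
})

#' Selected axial reference slice
#'
#' @slot index 0-based slice index along the superior--inferior axis.
#' @slot dgmAreaMm2 Deep-grey-matter area on that slice (mm^2).
#' @slot profile Per-slice DGM areas; element i corresponds to slice i-1.
#' @export
setClass("ReferenceSlice",
    representation(index = "integer", dgmAreaMm2 = "numeric",
                   profile = "numeric"))

setValidity("ReferenceSlice", function(object) {
    msg <- character()
    if (object@dgmAreaMm2 <= 0) msg <- c(msg, "dgmAreaMm2 must be positive")
    if (object@index < 0L || object@index >= length(object@profile))
        msg <- c(msg, "index outside profile range")
    else if (abs(object@profile[object@index + 1L] - max(object@profile)) > 1e-9)
        msg <- c(msg, "index must be an argmax of the profile")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom
## ---------------------------------------------------------------------------

#' Specification of a synthetic fetal-brain phantom
#'
#' See \code{\link{phantomSpec}} for defaults and units.
#' @export
setClass("PhantomSpec",
    representation(shape = "integer", spacing = "numeric",
                   rightWidthMm = "numeric", leftWidthMm = "numeric",
                   ventricleLengthMm = "numeric", rotationDeg = "numeric",
                   dgmSlice = "integer", plexus = "logical", csp = "logical",
                   noiseSd = "numeric", seed = "integer",
                   orientation = "character"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 8L))
        msg <- c(msg, "shape must be 3 integers >= 8")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive numbers")
    w <- c(object@rightWidthMm, object@leftWidthMm)
    if (any(w >= object@ventricleLengthMm))
        msg <- c(msg, "widths must be smaller than ventricleLengthMm")
    if (any(w < 2 * max(object@spacing[1:2])))
        msg <- c(msg, "widths must be at least 2 in-plane voxels")
    if (object@dgmSlice < 0L || object@dgmSlice >= object@shape[3L])
        msg <- c(msg, "dgmSlice outside the volume z range")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth emitted with a phantom
#'
#' @slot rightWidthMm,leftWidthMm Widths as realized after voxelization
#'   (requested width snapped to a whole number of in-plane voxels).
#' @slot referenceSlice 0-based slice index of maximal DGM area.
#' @slot plexusCentroids Named list (right, left) of 0-based voxel coordinates
#'   of the embedded glomus centres (NULL when \code{plexus} is off).
#' @slot componentCountOnSlice Number of 8-connected ventricle components on
#'   the reference slice, counted from the emitted label array.
#' @export
setClass("PhantomTruth",
    representation(rightWidthMm = "numeric", leftWidthMm = "numeric",
                   referenceSlice = "integer", plexusCentroids = "list",
                   componentCountOnSlice = "integer"))

## ---------------------------------------------------------------------------
## Classification and configuration
## ---------------------------------------------------------------------------

#' Per-case ventriculomegaly classification
#' @export
setClass("CaseClassification",
    representation(rightMm = "numeric", leftMm = "numeric",
                   caseLabel = "character", rightGrade = "character",
                   leftGrade = "character", asymmetryMm = "numeric",
                   asymmetryFlag = "logical"))

#' Agreement statistics between raters
#'
#' @slot pairStats One row per rater pair: mean absolute differences (right,
#'   left, pooled), squared Pearson correlations, paired t over the pooled
#'   ventricles, and the within-threshold count at \code{epsilon}.
#' @slot perCase Per-case absolute differences for every pair and side.
#' @slot raterSummary Per-rater, per-side mean and sample SD.
#' @slot epsilonMm The agreement threshold used (mm).
#' @export
setClass("AgreementReport",
    representation(pairStats = "data.frame", perCase = "data.frame",
                   raterSummary = "data.frame", epsilonMm = "numeric"))

#' Pipeline run configuration
#'
#' All clinical thresholds used anywhere in the pipeline live here: the 10 mm
#' ventriculomegaly cut-off, the (10, 13, 15) mm severity edges, the 2.4 mm
#' asymmetry allowance and the 1.7 mm agreement threshold.
#' @export
setClass("RunConfig",
    representation(mode = "character", epsilonMm = "numeric",
                   vmThresholdMm = "numeric", severityEdgesMm = "numeric",
                   asymmetryMm = "numeric", seed = "integer",
                   logLevel = "character"))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (!object@mode %in% c("minrect", "plexus_margin", "auto"))
        msg <- c(msg, "mode must be minrect, plexus_margin or auto")
    if (object@epsilonMm <= 0) msg <- c(msg, "epsilonMm must be positive")
    if (object@vmThresholdMm <= 0) msg <- c(msg, "vmThresholdMm must be positive")
    if (object@asymmetryMm <= 0) msg <- c(msg, "asymmetryMm must be positive")
    if (length(object@severityEdgesMm) != 3L ||
        any(diff(object@severityEdgesMm) <= 0))
        msg <- c(msg, "severityEdgesMm not increasing")
    if (!object@logLevel %in% c("quiet", "info", "debug"))
        msg <- c(msg, "logLevel must be quiet, info or debug")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
    cat(sprintf("VolumeGrid %s, spacing %s mm, orientation %s\n",
        paste(dim(object@data), collapse = "x"),
        paste(format(object@spacing), collapse = "x"), object@orientation))
})

setMethod("show", "LabelVolume", function(object) {
    tab <- table(factor(as.vector(object@labels), levels = object@labelScheme,
                        labels = names(object@labelScheme)))
    cat(sprintf("LabelVolume %s, spacing %s mm, orientation %s\n",
        paste(dim(object@labels), collapse = "x"),
        paste(format(object@spacing), collapse = "x"), object@orientation))
    nz <- tab[tab > 0]
    cat("  voxels:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
})

setMethod("show", "PlanarMask", function(object) {
    cat(sprintf("PlanarMask %s, %d pixels, slice %d, spacing %s mm\n",
        paste(dim(object@mask), collapse = "x"), sum(object@mask),
        object@sliceIndex, paste(format(object@spacing), collapse = "x")))
})

setMethod("show", "RotatedRect", function(object) {
    cat(sprintf("RotatedRect %.2f x %.2f mm at (%.1f, %.1f), angle %.1f deg\n",
        object@longSideMm, object@shortSideMm, object@center[1L],
        object@center[2L], object@angleDeg))
})

setMethod("show", "VentricleMeasurement", function(object) {
    cat(sprintf("%s ventricle: %.2f mm (%s, slice %d%s)\n",
        object@side, object@widthMm, object@method, object@sliceIndex,
        if (object@plexusDetected) ", plexus detected" else ""))
})

setMethod("show", "ReferenceSlice", function(object) {
    cat(sprintf("ReferenceSlice %d (DGM area %.2f mm^2 over %d slices)\n",
        object@index, object@dgmAreaMm2, length(object@profile)))
})

setMethod("show", "CaseClassification", function(object) {
    cat(sprintf("Case: %s (right %.2f mm [%s], left %.2f mm [%s], asymmetry %.2f mm%s)\n",
        object@caseLabel, object@rightMm, object@rightGrade, object@leftMm,
        object@leftGrade, object@asymmetryMm,
        if (object@asymmetryFlag) ", flagged" else ""))
})

setMethod("show", "PhantomTruth", function(object) {
    cat(sprintf("PhantomTruth: right %.2f mm, left %.2f mm, reference slice %d, %d component(s)\n",
        object@rightWidthMm, object@leftWidthMm, object@referenceSlice,
        object@componentCountOnSlice))
})

setMethod("show", "AgreementReport", function(object) {
    cat(sprintf("AgreementReport: %d pair(s), epsilon %.2f mm\n",
        nrow(object@pairStats), object@epsilonMm))
    print(object@pairStats, digits = 4)
})

setMethod("show", "RunConfig", function(object) {
    cat(sprintf(
        "RunConfig: mode=%s, VM threshold=%.1f mm, severity edges=(%s) mm,\n  asymmetry=%.1f mm, epsilon=%.1f mm, seed=%d, logLevel=%s\n",
        object@mode, object@vmThresholdMm,
        paste(format(object@severityEdgesMm), collapse = ", "),
        object@asymmetryMm, object@epsilonMm, object@seed, object@logLevel))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Voxel spacing of a volume
#' @param x A \code{VolumeGrid} or \code{LabelVolume}.
#' @return Numeric length-3 (mm per voxel).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' Anatomical orientation code of a volume
#' @param x A \code{VolumeGrid} or \code{LabelVolume}.
#' @return Three-letter code such as \code{"RAS"}.
#' @export
setGeneric("axisCode", function(x) standardGeneric("axisCode"))
#' @rdname axisCode
setMethod("axisCode", "VolumeGrid", function(x) x@orientation)
#' @rdname axisCode
setMethod("axisCode", "LabelVolume", function(x) x@orientation)

#' Label scheme of a label volume
#' @param x A \code{LabelVolume}.
#' @return Named integer vector of tissue codes.
#' @export
setGeneric("labelScheme", function(x) standardGeneric("labelScheme"))
#' @rdname labelScheme
setMethod("labelScheme", "LabelVolume", function(x) x@labelScheme)

#' Measured width in mm
#' @param x A \code{VentricleMeasurement}.
#' @export
setGeneric("widthMm", function(x) standardGeneric("widthMm"))
#' @rdname widthMm
setMethod("widthMm", "VentricleMeasurement", function(x) x@widthMm)
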
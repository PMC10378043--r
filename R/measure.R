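#' Measure one ventricle's atrial width
#'
#' Refines the component by mean-intensity binarization, fits the
#' minimum-area rectangle, and reports a width in mm. Modes:
#' \describe{
#'   \item{\code{minrect}}{(default, deterministic) the short side of the
#'     minimum-area rectangle: the extent perpendicular to the ventricle's
#'     long axis after reorientation.}
#'   \item{\code{plexus_margin}}{the measurement line is moved along the
#'     long axis to the margin of the removed choroid-plexus cluster nearest
#'     the component centroid, and the width is the perpendicular extent of
#'     the refined mask at that station; falls back to \code{minrect} when
#'     binarization removed no plexus-sized cluster.}
#'   \item{\code{auto}}{\code{plexus_margin} when a plexus was detected,
#'     otherwise \code{minrect}.}
#' }
#'
#' @param intensity Co-registered \code{\linkS4class{VolumeGrid}}.
#' @param component A \code{\linkS4class{PlanarMask}} holding one ventricle.
#' @param mode Measurement mode (see above).
#' @param orientation Orientation code of the parent volume; used to locate
#'   the posterior end for \code{plexus_margin}. When \code{NULL}, the
#'   removed cluster farthest from the component centroid is used instead.
#' @param side \code{"left"} or \code{"right"} (provenance only).
#' @return A \code{\linkS4class{VentricleMeasurement}}.
#' @export
measureWidth <- function(intensity, component,
                         mode = c("minrect", "plexus_margin", "auto"),
                         orientation = NULL, side = "right") {
    mode <- match.arg(mode)
    bin <- .binarizeDetails(intensity, component)
    refined <- bin$mask
    if (!any(refined@mask))
        stop("measurement: refined mask is empty after fallback")
    rect <- minAreaRect(refined)
    pitch <- .isotropicPitch(component@spacing, "measurement")

    useMargin <- switch(mode,
        minrect = FALSE,
        plexus_margin = TRUE,
        auto = bin$plexusDetected)

    width <- rect@shortSideMm
    method <- "minrect"
    if (useMargin) {
        w <- .plexusMarginWidth(refined, bin$removed, rect, pitch, orientation)
        if (!is.null(w)) { width <- min(w, rect@longSideMm); method <- "plexus_margin" }
    }
    new("VentricleMeasurement", side = side, widthMm = width, method = method,
        sliceIndex = component@sliceIndex, plexusDetected = bin$plexusDetected,
        rect = rect, thresholdUsed = bin$threshold)
}

# Width at the choroid-plexus margin. Rotate pixel-centre coordinates so the
# rectangle's long side is horizontal; pick the removed cluster nearest the
# posterior end; measure the vertical extent of the refined mask at the
# horizontal station of that cluster's margin closest to the component
# centroid. Returns NULL when there is no plexus-sized removed cluster.
.plexusMarginWidth <- function(refined, removed, rect, pitch, orientation,
                               minArea = 4L) {
    rl <- .labelComponents8(removed)
    sizes <- tabulate(rl)
    big <- which(sizes >= minArea)
    if (!length(big)) return(NULL)

    theta <- rect@angleDeg * pi / 180
    rot <- function(idx) {
        x <- (idx[, 2L] - 1) * pitch; y <- (idx[, 1L] - 1) * pitch
        cbind(u = x * cos(theta) + y * sin(theta),
              v = -x * sin(theta) + y * cos(theta))
    }
    refUV <- rot(which(refined@mask, arr.ind = TRUE))
    centroidU <- mean(refUV[, "u"])

    ## posterior sign along the rotated long axis
    postSign <- 0
    if (!is.null(orientation)) {
        ax <- .axisInfo(orientation)
        apDim <- match(ax$apAxis, refined@axes)
        if (!is.na(apDim)) {
            ## unit posterior vector in (x=col, y=row) mm coordinates
            pvec <- c(0, 0)
            pvec[ifelse(apDim == 1L, 2L, 1L)] <- if (ax$apPositiveIsAnterior) -1 else 1
            postSign <- sign(pvec[1L] * cos(theta) + pvec[2L] * sin(theta))
        }
    }

    clU <- vapply(big, function(k) {
        uv <- rot(which(rl == k, arr.ind = TRUE))
        mean(uv[, "u"])
    }, numeric(1))
    pick <- if (postSign != 0) big[which.max(postSign * clU)]
            else big[which.max(abs(clU - centroidU))]

    uv <- rot(which(rl == pick, arr.ind = TRUE))
    station <- if (mean(uv[, "u"]) >= centroidU) min(uv[, "u"]) else max(uv[, "u"])

    ## vertical extent of the refined mask at that station (widen the window
    ## by one pitch at a time if the exact column is empty)
    for (half in (1:4) * pitch / 2) {
        inCol <- abs(refUV[, "u"] - station) <= half
        if (any(inCol))
            return(diff(range(refUV[inCol, "v"])) + pitch)
    }
    NULL
}

#' Measure both lateral ventricles of a case
#'
#' End-to-end orchestration on a co-registered intensity/label pair:
#' reference-slice selection, 8-connected component extraction, laterality
#' assignment and per-side width measurement. Both measurements refer to the
#' same reference slice.
#'
#' @param intensity A \code{\linkS4class{VolumeGrid}}.
#' @param labels The matching \code{\linkS4class{LabelVolume}}.
#' @param mode Measurement mode, see \code{\link{measureWidth}}.
#' @return List with elements \code{right}, \code{left}
#'   (\code{\linkS4class{VentricleMeasurement}}) and \code{slice}
#'   (\code{\linkS4class{ReferenceSlice}}).
#' @export
measureCase <- function(intensity, labels,
                        mode = c("minrect", "plexus_margin", "auto")) {
    mode <- match.arg(mode)
    stopifnot(is(intensity, "VolumeGrid"), is(labels, "LabelVolume"))
    if (!identical(dim(intensity@data), dim(labels@labels)))
        stop("measurement: intensity and label volumes have different shapes")
    slice <- selectReferenceSlice(labels)
    comps <- extractComponents(labels, slice)
    lat <- assignLaterality(comps, axisCode(labels))
    ori <- axisCode(labels)
    list(right = measureWidth(intensity, lat$right, mode, ori, side = "right"),
         left  = measureWidth(intensity, lat$left, mode, ori, side = "left"),
         slice = slice)
}
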
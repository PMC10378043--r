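# Shared internals for the mean-intensity refinement step. The segmented
# ventricle carries a dark fringe (partial-volume margin) and the choroid
# plexus glomus, both of which would corrupt a linear width; thresholding at
# the component's mean intensity removes them because CSF is the brightest
# tissue on T2-weighted images.

.intensitySlice <- function(intensity, component) {
    stopifnot(is(intensity, "VolumeGrid"), is(component, "PlanarMask"))
    siAxis <- setdiff(1:3, component@axes)
    sl <- .extractSlice(intensity@data, siAxis, component@sliceIndex)
    if (!identical(dim(sl), dim(component@mask)))
        stop("binarization: intensity volume is not co-registered with the component")
    sl
}

# Full detail: refined mask, threshold, removed pixels, plexus flag.
.binarizeDetails <- function(intensity, component, minArea = 4L) {
    sl <- .intensitySlice(intensity, component)
    m <- component@mask
    if (!any(m)) stop("binarization: empty component")
    thr <- mean(sl[m])
    kept <- m & (sl >= thr)
    fellBack <- FALSE
    if (any(kept)) {
        kept <- .largestComponent8(kept)
    } else {
        kept <- m
        fellBack <- TRUE
    }
    removed <- m & !kept
    plexusDetected <- FALSE
    if (!fellBack && any(removed)) {
        rl <- .labelComponents8(removed)
        plexusDetected <- any(tabulate(rl) >= minArea)
    }
    list(mask = new("PlanarMask", mask = kept, spacing = component@spacing,
                    sliceIndex = component@sliceIndex, axes = component@axes),
         threshold = thr, removed = removed, plexusDetected = plexusDetected)
}

#' Refine a ventricle component by mean-intensity thresholding
#'
#' Computes the mean intensity m over the component's pixels and keeps
#' exactly the pixels with intensity >= m, then retains only the largest
#' 8-connected piece of the result. If thresholding empties the mask the
#' input component is returned unchanged. The output is always a subset of
#' the input, and re-applying the stored threshold to the kept pixels leaves
#' the set unchanged.
#'
#' @param intensity Co-registered \code{\linkS4class{VolumeGrid}}.
#' @param component A \code{\linkS4class{PlanarMask}} (one ventricle).
#' @return A refined \code{PlanarMask}; the threshold is attached as
#'   attribute \code{"threshold"} and the plexus flag as
#'   attribute \code{"plexusDetected"}.
#' @export
binarizeSegment <- function(intensity, component) {
    d <- .binarizeDetails(intensity, component)
    out <- d$mask
    attr(out, "threshold") <- d$threshold
    attr(out, "plexusDetected") <- d$plexusDetected
    out
}
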
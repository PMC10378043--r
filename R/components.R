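#' Connected ventricle components on the reference slice
#'
#' Labels the ventricle class on the reference slice with 8-connectivity and
#' returns one \code{\linkS4class{PlanarMask}} per component, sorted by
#' descending area. On a typical slice these are the left ventricle, the
#' right ventricle and (when present) the cavum septum pellucidum. Components
#' below \code{minArea} pixels are treated as speckle and discarded (with a
#' message).
#'
#' @param labels A \code{\linkS4class{LabelVolume}}.
#' @param slice A \code{\linkS4class{ReferenceSlice}} (or 0-based slice index).
#' @param minArea Minimum component area in pixels (default 4).
#' @return List of \code{PlanarMask}, largest first.
#' @export
extractComponents <- function(labels, slice, minArea = 4L) {
    stopifnot(is(labels, "LabelVolume"))
    idx0 <- if (is(slice, "ReferenceSlice")) slice@index else as.integer(slice)
    ax <- .axisInfo(labels@orientation)
    inplane <- sort(setdiff(1:3, ax$siAxis))
    vent <- labels@labelScheme[["ventricles"]]
    sl <- .extractSlice(labels@labels, ax$siAxis, idx0) == vent
    if (!any(sl))
        stop("component extraction: no ventricle on reference slice")
    lab <- .labelComponents8(sl)
    sizes <- tabulate(lab)
    keep <- which(sizes >= minArea)
    if (length(keep) < length(sizes))
        message(sprintf("component extraction: discarded %d component(s) below %d px",
                        length(sizes) - length(keep), minArea))
    if (!length(keep))
        stop("component extraction: no ventricle component above the area floor")
    keep <- keep[order(-sizes[keep])]
    lapply(keep, function(k)
        new("PlanarMask", mask = lab == k,
            spacing = labels@spacing[inplane],
            sliceIndex = idx0, axes = as.integer(inplane)))
}

#' Assign left/right laterality (and the septal component)
#'
#' The two largest components are taken as the lateral ventricles; the one
#' whose centroid lies on the subject-left side (per the orientation code) is
#' \code{left}. A third component whose centroid lies between the two along
#' the left--right axis is returned as \code{csp}. If both large components
#' fall on the same side of the slice midline a warning is raised and the
#' assignment falls back to relative position.
#'
#' @param components List of \code{\linkS4class{PlanarMask}} from
#'   \code{\link{extractComponents}} (largest first).
#' @param orientation Orientation code of the parent volume.
#' @return List with elements \code{left}, \code{right} and \code{csp}
#'   (\code{NULL} when absent).
#' @export
assignLaterality <- function(components, orientation) {
    if (length(components) < 2L)
        stop("laterality: cannot separate ventricles (fewer than 2 components)")
    ax <- .axisInfo(orientation)
    axes <- components[[1L]]@axes
    lrDim <- match(ax$lrAxis, axes)
    if (is.na(lrDim))
        stop("laterality: components do not span the left-right axis")
    coord <- vapply(components, function(p) .maskCentroid(p@mask)[lrDim],
                    numeric(1))
    ## subject-left is at smaller index when increasing index points right
    leftIsSmaller <- ax$lrPositiveIsRight
    mid <- (dim(components[[1L]]@mask)[lrDim] + 1) / 2
    if (sign(coord[1L] - mid) == sign(coord[2L] - mid) &&
        abs(coord[1L] - mid) > 1e-9 && abs(coord[2L] - mid) > 1e-9)
        warning("laterality: both major components lie on the same side of the midline; assigning by relative position")
    firstIsLeft <- if (leftIsSmaller) coord[1L] < coord[2L] else coord[1L] > coord[2L]
    out <- if (firstIsLeft)
        list(left = components[[1L]], right = components[[2L]], csp = NULL)
    else
        list(left = components[[2L]], right = components[[1L]], csp = NULL)
    if (length(components) >= 3L) {
        lo <- min(coord[1:2]); hi <- max(coord[1:2])
        for (k in 3:length(components)) {
            if (coord[k] > lo && coord[k] < hi) { out$csp <- components[[k]]; break }
        }
    }
    out
}
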
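#' Per-slice deep-grey-matter area profile
#'
#' For every axial slice (perpendicular to the superior--inferior axis as
#' identified by the orientation code), the deep-grey-matter area in mm^2:
#' voxel count times in-plane voxel area. The thalamus belongs to the DGM
#' class, so the slice maximizing this profile approximates the clinical
#' thalamic measurement plane.
#'
#' @param labels A \code{\linkS4class{LabelVolume}}.
#' @return Numeric vector of areas; element \code{i} corresponds to 0-based
#'   slice \code{i - 1}. Slices without DGM yield 0.
#' @export
dgmAreaProfile <- function(labels) {
    stopifnot(is(labels, "LabelVolume"))
    ax <- .axisInfo(labels@orientation)
    dgm <- labels@labelScheme[["deep_grey_matter"]]
    inplane <- setdiff(1:3, ax$siAxis)
    pixArea <- prod(labels@spacing[inplane])
    counts <- apply(labels@labels == dgm, ax$siAxis, sum)
    as.numeric(counts) * pixArea
}

#' Select the axial reference slice for ventricle measurement
#'
#' The measurement plane is the axial slice with the largest segmented
#' deep-grey-matter area. Ties are broken towards the smallest (most
#' inferior-indexed) slice; no smoothing is applied to the profile.
#'
#' @param labels A \code{\linkS4class{LabelVolume}} with at least one DGM voxel.
#' @return A \code{\linkS4class{ReferenceSlice}}.
#' @export
selectReferenceSlice <- function(labels) {
    profile <- dgmAreaProfile(labels)
    if (all(profile == 0))
        stop("reference slice selection: cannot select reference slice, no DGM voxels")
    idx <- which.max(profile)           # first maximum = smallest index
    ax <- .axisInfo(labels@orientation)
    vent <- labels@labelScheme[["ventricles"]]
    if (!any(.extractSlice(labels@labels, ax$siAxis, idx - 1L) == vent))
        message(sprintf(
            "note: reference slice %d contains no ventricle voxels", idx - 1L))
    new("ReferenceSlice", index = idx - 1L, dgmAreaMm2 = profile[idx],
        profile = profile)
}
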
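#' FeTA seven-tissue label scheme
#'
#' Integer codes for the seven fetal brain tissue classes plus background,
#' following the Fetal Tissue Annotation (FeTA) challenge convention. The
#' source segmentation protocol lists the tissue categories but not their
#' integer codes, so this mapping is a documented package choice and can be
#' overridden per volume (see \code{\link{loadLabelScheme}}).
#'
#' @return Named integer vector: background 0, external CSF 1, grey matter 2,
#'   white matter 3, ventricles 4, cerebellum 5, deep grey matter 6,
#'   brainstem 7.
#' @export
#' @examples
#' fetaLabelScheme()[["ventricles"]]
fetaLabelScheme <- function() {
    c(background = 0L, csf_ext = 1L, grey_matter = 2L, white_matter = 3L,
      ventricles = 4L, cerebellum = 5L, deep_grey_matter = 6L, brainstem = 7L)
}

#' Load a label scheme from a JSON side-file
#'
#' The file must be a flat JSON object mapping tissue names to integer codes,
#' and must contain at least the keys \code{background}, \code{ventricles}
#' and \code{deep_grey_matter} (the classes the workflow relies on).
#'
#' @param path Path to a JSON file.
#' @return Named integer vector usable as a \code{labelScheme}.
#' @export
loadLabelScheme <- function(path) {
    if (!file.exists(path)) stop(sprintf("label scheme file not found: %s", path))
    raw <- jsonlite::fromJSON(path)
    if (!is.list(raw) && !is.numeric(raw)) stop("label scheme must be a flat JSON object")
    vals <- unlist(raw)
    if (any(vals != round(vals))) stop("label scheme codes must be integers")
    scheme <- structure(as.integer(vals), names = names(vals))
    need <- c("background", "ventricles", "deep_grey_matter")
    miss <- setdiff(need, names(scheme))
    if (length(miss))
        stop(sprintf("label scheme is missing required class(es): %s",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(scheme)) stop("label scheme codes must be unique")
    scheme
}

## ---------------------------------------------------------------------------
## NIfTI reading and writing
## ---------------------------------------------------------------------------

.orientationFromHeader <- function(img, path) {
    hdr <- RNifti::niftiHeader(img)
    if (hdr$qform_code == 0L && hdr$sform_code == 0L) {
        warning(sprintf(
            "%s carries no valid qform/sform; assuming RAS orientation", path))
        return("RAS")
    }
    RNifti::orientation(img)
}

.readNiftiArray <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4L] == 1L) { # trailing singleton volume axis
        img2 <- array(as.vector(img), dim = d[1:3])
        attributes(img2)$pixdim <- NULL
        ori <- .orientationFromHeader(img, path)
        return(list(data = img2, spacing = RNifti::pixdim(img)[1:3],
                    orientation = ori))
    }
    if (length(d) != 3L)
        stop(sprintf("%s: expected 3D data, got %d dimension(s)", path, length(d)))
    list(data = array(as.vector(img), dim = d),
         spacing = RNifti::pixdim(img)[1:3],
         orientation = .orientationFromHeader(img, path))
}

#' Read a NIfTI intensity volume
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \code{\linkS4class{VolumeGrid}}. Spacing and orientation are
#'   taken from the header; if the header carries no valid transform, RAS is
#'   assumed with a warning.
#' @export
readVolumeGrid <- function(path) {
    x <- .readNiftiArray(path)
    new("VolumeGrid", data = x$data + 0.0, spacing = x$spacing,
        orientation = x$orientation)
}

#' Read a NIfTI tissue label volume
#'
#' Label data are cast to integers only when every voxel value is a whole
#' number; any value outside the scheme aborts with a message naming the
#' offending value.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param scheme Named integer label scheme (default \code{\link{fetaLabelScheme}}).
#' @return A \code{\linkS4class{LabelVolume}}.
#' @export
readLabelVolume <- function(path, scheme = fetaLabelScheme()) {
    x <- .readNiftiArray(path)
    v <- as.vector(x$data)
    if (any(v != round(v)))
        stop(sprintf("%s: label volume contains non-integer voxel value %g",
                     path, v[which(v != round(v))[1L]]))
    labs <- array(as.integer(round(v)), dim = dim(x$data))
    bad <- setdiff(unique(as.vector(labs)), scheme)
    if (length(bad))
        stop(sprintf("%s: label value(s) %s not in the label scheme {%s}",
                     path, paste(sort(bad), collapse = ", "),
                     paste(sort(scheme), collapse = ", ")))
    new("LabelVolume", labels = labs, spacing = x$spacing,
        orientation = x$orientation, labelScheme = scheme)
}

# World-direction unit vector for one orientation letter (NIfTI RAS+ world).
.letterDirection <- function(letter) {
    switch(letter,
        R = c(1, 0, 0), L = c(-1, 0, 0),
        A = c(0, 1, 0), P = c(0, -1, 0),
        S = c(0, 0, 1), I = c(0, 0, -1))
}

.writeNiftiArray <- function(data, spacing, orientation, path) {
    if (length(dim(data)) != 3L || any(dim(data) == 0L))
        stop("cannot write: data must be a non-empty 3D array")
    .axisInfo(orientation) # validate
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- spacing
    aff <- diag(4)
    letters3 <- strsplit(toupper(orientation), "")[[1L]]
    for (j in 1:3) aff[1:3, j] <- .letterDirection(letters3[j]) * spacing[j]
    RNifti::sform(img) <- structure(aff, code = 2L)
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
        stop(sprintf("could not write NIfTI file: %s", path))
    invisible(path)
}

#' Write a label volume to NIfTI
#'
#' Round-trips through \code{\link{readLabelVolume}}: labels bit-exactly,
#' spacing to float32 precision, orientation exactly.
#'
#' @param volume A \code{\linkS4class{LabelVolume}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @export
writeLabelVolume <- function(volume, path) {
    stopifnot(is(volume, "LabelVolume"))
    .writeNiftiArray(volume@labels, volume@spacing, volume@orientation, path)
}

#' Write an intensity volume to NIfTI
#' @param volume A \code{\linkS4class{VolumeGrid}}.
#' @param path Output path.
#' @export
writeVolumeGrid <- function(volume, path) {
    stopifnot(is(volume, "VolumeGrid"))
    .writeNiftiArray(volume@data, volume@spacing, volume@orientation, path)
}

## ---------------------------------------------------------------------------
## Series ranking
## ---------------------------------------------------------------------------

#' Rank acquired series by segmented brain volume
#'
#' Reproduces the series-selection step of the upstream reconstruction
#' workflow: series are sorted by the physical volume of non-background
#' voxels (count times voxel volume) and the top \code{k} are returned. Ties
#' are broken by \code{seriesId} ascending.
#'
#' @param stacks List of \code{\linkS4class{SeriesStack}} objects.
#' @param k Number of series to keep (clamped to the number available).
#' @return List of at most \code{k} stacks, descending by segmented volume.
#' @export
rankSeries <- function(stacks, k) {
    if (!length(stacks)) stop("rankSeries: empty stack list")
    stopifnot(k >= 1)
    vol <- vapply(stacks, function(s) {
        sum(s@labelVolume@labels != 0L) * prod(s@labelVolume@spacing)
    }, numeric(1))
    ids <- vapply(stacks, function(s) s@seriesId, character(1))
    ord <- order(-vol, ids)
    stacks[ord][seq_len(min(k, length(stacks)))]
}

## ---------------------------------------------------------------------------
## Measurement tables
## ---------------------------------------------------------------------------

#' Read a per-case, per-rater width table
#'
#' Expects a CSV with columns \code{case_id}, \code{group} and one
#' \code{<rater>_right} / \code{<rater>_left} pair per rater; widths are in
#' mm. The bundled fixture (see \code{\link{bundledMeasurementTable}}) holds
#' the published 22-case comparison of a general radiologist, a
#' neuroradiologist and the automated measurement.
#'
#' @param path CSV file path.
#' @return A \code{data.frame} with attribute \code{"raters"} listing the
#'   rater prefixes found.
#' @export
readMeasurementTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) stop("measurement table: no cases")
    need <- c("case_id", "group")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("measurement table: missing column(s) %s",
                     paste(miss, collapse = ", ")))
    rs <- grep("_right$", names(df), value = TRUE)
    raters <- sub("_right$", "", rs)
    if (!length(raters))
        stop("measurement table: no <rater>_right/<rater>_left column pairs")
    for (r in raters) {
        for (col in paste0(r, c("_right", "_left"))) {
            if (!col %in% names(df))
                stop(sprintf("measurement table: missing column %s", col))
            if (!is.numeric(df[[col]]))
                stop(sprintf("measurement table: non-numeric width in %s", col))
            if (any(!is.finite(df[[col]])) || any(df[[col]] <= 0))
                stop(sprintf("measurement table: widths in %s must be positive", col))
        }
    }
    if (!all(df$group %in% c("normal", "abnormal")))
        stop("measurement table: group must be 'normal' or 'abnormal'")
    attr(df, "raters") <- raters
    df
}

#' Path to the bundled rater-comparison table
#'
#' The packaged CSV \code{tables_2_3.csv} holds the published width
#' measurements of 22 fetal MRI cases (10 normal, 12 with ventriculomegaly)
#' by three raters: \code{gen} (general radiologist), \code{neuro}
#' (neuroradiologist) and \code{ai} (the automated workflow).
#'
#' @return File path inside the installed package.
#' @export
bundledMeasurementTable <- function() {
    system.file("extdata", "tables_2_3.csv", package = "ventrimetry",
                mustWork = TRUE)
}

#' Rater prefixes present in a measurement table
#' @param table A table from \code{\link{readMeasurementTable}}.
#' @export
raterNames <- function(table) {
    r <- attr(table, "raters")
    if (is.null(r)) sub("_right$", "", grep("_right$", names(table), value = TRUE))
    else r
}
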
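#' Specify a synthetic fetal-brain phantom
#'
#' Builds the parameter object consumed by \code{\link{makePhantom}}. The
#' phantom emulates the anatomy the measurement workflow relies on: an
#' ellipsoidal white-matter brain with a thin cortical grey-matter shell, two
#' ventricle-labelled elliptic cylinders whose axial cross-section at the
#' reference slice has a controlled minor diameter (the ground-truth atrial
#' width), a deep-grey-matter blob whose axial area peaks exactly at
#' \code{dgmSlice}, an optional midline cavum septum pellucidum component
#' carrying the ventricle label, and an optional dark choroid-plexus glomus
#' embedded in the posterior third of each ventricle.
#'
#' Geometry (all mm): ventricle centres sit 13 mm either side of the midline,
#' 4 mm posterior of the volume centre, with major axis along
#' anterior--posterior rotated by \code{rotationDeg} within the axial plane
#' (mirrored between the two sides). The requested width is snapped to a whole
#' number of in-plane voxels and the cylinder is positioned so that, at zero
#' rotation, the rasterized minor diameter equals that voxel count exactly.
#'
#' @param shape Volume dimensions in voxels (default \code{c(128, 128, 64)}).
#' @param spacing Voxel size in mm (default 0.5 isotropic, matching
#'   super-resolution-reconstructed fetal volumes).
#' @param rightWidthMm,leftWidthMm Target atrial widths (minor diameters), mm.
#' @param ventricleLengthMm Major-axis length of each ventricle, mm.
#' @param rotationDeg In-plane rotation of the ventricle major axis, degrees.
#' @param dgmSlice 0-based index of the slice where DGM area is maximal.
#' @param plexus Embed a low-intensity glomus in each ventricle.
#' @param csp Embed a small midline ventricle-labelled component.
#' @param noiseSd Additive Gaussian intensity noise SD (clipped at zero).
#' @param seed RNG seed for the noise; identical spec + seed gives
#'   bit-identical volumes.
#' @return A \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 64L), spacing = c(0.5, 0.5, 0.5),
                        rightWidthMm = 8, leftWidthMm = 8,
                        ventricleLengthMm = 20, rotationDeg = 0,
                        dgmSlice = 32L, plexus = TRUE, csp = TRUE,
                        noiseSd = 2, seed = 42L) {
    new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
        rightWidthMm = rightWidthMm, leftWidthMm = leftWidthMm,
        ventricleLengthMm = ventricleLengthMm, rotationDeg = rotationDeg,
        dgmSlice = as.integer(dgmSlice), plexus = plexus, csp = csp,
        noiseSd = noiseSd, seed = as.integer(seed))
}

# Voxel centres sit at index*spacing (0-based). For an exact rasterized
# diameter of n voxels the ellipse centre must sit on a voxel centre when n
# is odd and on a voxel boundary when n is even.
.snapCenterVox <- function(baseVox, n) {
    if (n %% 2L == 1L) round(baseVox) else round(baseVox - 0.5) + 0.5
}

.ellipsoid <- function(X, Y, Z, ctr, semi) {
    ((X - ctr[1L]) / semi[1L])^2 + ((Y - ctr[2L]) / semi[2L])^2 +
        ((Z - ctr[3L]) / semi[3L])^2 < 1
}

#' Generate a synthetic phantom volume pair with ground truth
#'
#' @param spec A \code{\linkS4class{PhantomSpec}}.
#' @return List with elements \code{intensity} (\code{VolumeGrid}),
#'   \code{labels} (\code{LabelVolume}) and \code{truth}
#'   (\code{\linkS4class{PhantomTruth}}). Intensities: 200 for CSF-filled
#'   structures, 100 for parenchyma, 40 for the plexus glomus (at most half
#'   the within-ventricle mean, so the mean-intensity binarization provably
#'   excludes it), plus clipped Gaussian noise.
#' @export
makePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    nx <- spec@shape[1L]; ny <- spec@shape[2L]; nz <- spec@shape[3L]
    sx <- spec@spacing[1L]; sy <- spec@spacing[2L]; sz <- spec@spacing[3L]
    ext <- (spec@shape - 1L) * spec@spacing
    c0 <- ext / 2                       # volume centre, mm

    a  <- spec@ventricleLengthMm / 2    # major semi-axis
    nR <- as.integer(round(spec@rightWidthMm / sx))
    nL <- as.integer(round(spec@leftWidthMm / sx))
    bR <- nR * sx / 2; bL <- nL * sx / 2
    xOff <- 13; yOff <- -4; zHalf <- 6  # ventricle placement, mm
    zc <- spec@dgmSlice * sz

    ## feasibility
    reach <- max(a, bR, bL)
    if (xOff + reach > c0[1L] - 1 || abs(yOff) + a > c0[2L] - 1)
        stop("phantom: ventricle length/width does not fit inside shape")
    if (zc - zHalf < 0 || zc + zHalf > ext[3L])
        stop("phantom: ventricle does not fit inside the z range at dgmSlice")

    xi <- (0:(nx - 1L)) * sx; yj <- (0:(ny - 1L)) * sy; zk <- (0:(nz - 1L)) * sz
    dims <- c(nx, ny, nz)
    X <- array(xi, dims)
    Y <- array(rep(yj, each = nx), dims)
    Z <- array(rep(zk, each = nx * ny), dims)

    lab <- array(0L, dims)
    semiWM <- c(0.44 * ext[1L], 0.47 * ext[2L], 0.44 * ext[3L])
    lab[.ellipsoid(X, Y, Z, c0, semiWM * 1.07)] <- 2L   # cortical GM shell
    lab[.ellipsoid(X, Y, Z, c0, semiWM)] <- 3L          # white matter

    ## deep grey matter blob: per-slice discs whose radius follows an
    ## ellipsoidal profile, with the disc at dgmSlice enlarged by a fraction
    ## of a voxel so its rasterized area is strictly maximal (plain ellipsoid
    ## rasterization can tie between neighbouring slices)
    dgmCtr <- c(c0[1L], c0[2L] + 16, zc)
    dgmR <- 6; dgmZ <- 5
    if (dgmCtr[2L] + dgmR > ext[2L] || zc - dgmZ < 0 || zc + dgmZ > ext[3L])
        stop("phantom: DGM blob does not fit inside shape at dgmSlice")
    dz <- (zk - zc) / dgmZ
    rvec <- ifelse(abs(dz) < 1, dgmR * sqrt(pmax(0, 1 - dz^2)), 0)
    rvec[spec@dgmSlice + 1L] <- dgmR + 0.6 * max(sx, sy)
    radArr <- array(rep(rvec, each = nx * ny), dims)
    lab[(X - dgmCtr[1L])^2 + (Y - dgmCtr[2L])^2 < radArr^2] <- 6L

    cyVox <- round((c0[2L] + yOff) / sy)
    cy <- cyVox * sy

    ## optional midline CSP component (ventricle label)
    if (spec@csp)
        lab[.ellipsoid(X, Y, Z, c(c0[1L], cy, zc), c(1.2, 4, 3))] <- 4L

    ## the two lateral ventricles: rotated elliptic cylinders
    ventSide <- function(sideSign, n, b) {
        theta <- sideSign * spec@rotationDeg * pi / 180
        cxVox <- .snapCenterVox((c0[1L] + sideSign * xOff) / sx, n)
        cx <- cxVox * sx
        uMin <- (X - cx) * cos(theta) - (Y - cy) * sin(theta)
        uMaj <- (X - cx) * sin(theta) + (Y - cy) * cos(theta)
        mask <- (uMin / b)^2 + (uMaj / a)^2 < 1 & abs(Z - zc) <= zHalf
        ## glomus centre: inner margin one third of the semi-axis behind centre
        r <- min(2, 0.45 * b)
        um <- -(a / 3 + r)
        pCtr <- c(cx + sin(theta) * um, cy + cos(theta) * um, zc)
        list(mask = mask, plexusCtr = pCtr, plexusR = r)
    }
    right <- ventSide(+1, nR, bR)
    left  <- ventSide(-1, nL, bL)
    lab[right$mask] <- 4L
    lab[left$mask]  <- 4L

    ## intensities
    intens <- array(0, dims)
    intens[lab %in% c(2L, 3L, 6L)] <- 100
    intens[lab == 4L] <- 200
    plexusCentroids <- list()
    if (spec@plexus) {
        for (side in list(r = right, l = left)) {
            pm <- .ellipsoid(X, Y, Z, side$plexusCtr,
                             c(side$plexusR, side$plexusR, min(1.5, side$plexusR)))
            intens[pm & side$mask] <- 40
        }
        plexusCentroids <- list(
            right = as.integer(round(right$plexusCtr / spec@spacing)),
            left  = as.integer(round(left$plexusCtr / spec@spacing)))
    }
    if (spec@noiseSd > 0) {
        intens <- .withSeed(spec@seed, {
            n <- intens + stats::rnorm(length(intens), sd = spec@noiseSd)
            n[n < 0] <- 0
            n
        })
    }

    labels <- new("LabelVolume", labels = lab, spacing = spec@spacing,
                  orientation = "RAS", labelScheme = fetaLabelScheme())
    volume <- new("VolumeGrid", data = intens, spacing = spec@spacing,
                  orientation = "RAS")

    ventSlice <- .extractSlice(lab, 3L, spec@dgmSlice) == 4L
    nComp <- max(.labelComponents8(ventSlice), 0L)

    truth <- new("PhantomTruth",
                 rightWidthMm = nR * sx, leftWidthMm = nL * sx,
                 referenceSlice = spec@dgmSlice,
                 plexusCentroids = plexusCentroids,
                 componentCountOnSlice = as.integer(nComp))
    list(intensity = volume, labels = labels, truth = truth)
}

#' Slice of maximal deep-grey-matter voxel count
#'
#' Independent per-slice voxel count used to confirm a phantom's reference
#' slice; returns the 0-based argmax (smallest index on ties).
#'
#' @param labels A \code{\linkS4class{LabelVolume}}.
#' @return 0-based slice index along the superior--inferior axis.
#' @export
dgmPeakSlice <- function(labels) {
    stopifnot(is(labels, "LabelVolume"))
    ax <- .axisInfo(labels@orientation)
    dgm <- labels@labelScheme[["deep_grey_matter"]]
    nSlices <- dim(labels@labels)[ax$siAxis]
    counts <- vapply(seq_len(nSlices) - 1L, function(k)
        sum(.extractSlice(labels@labels, ax$siAxis, k) == dgm), numeric(1))
    if (all(counts == 0)) stop("dgmPeakSlice: volume contains no DGM voxels")
    which.max(counts) - 1L
}
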
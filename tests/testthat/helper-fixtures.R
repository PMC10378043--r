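# Shared fixture builders. All fixtures are generated in code; phantoms are
# memoised per parameter set because several test files reuse the same ones.

.phantomCache <- new.env(parent = emptyenv())

phantomFixture <- function(rightWidthMm = 8, leftWidthMm = 8, rotationDeg = 0,
                           plexus = TRUE, csp = TRUE, seed = 42L,
                           dgmSlice = 32L, noiseSd = 2) {
    key <- paste(rightWidthMm, leftWidthMm, rotationDeg, plexus, csp, seed,
                 dgmSlice, noiseSd, sep = "|")
    if (is.null(.phantomCache[[key]]))
        .phantomCache[[key]] <- makePhantom(phantomSpec(
            rightWidthMm = rightWidthMm, leftWidthMm = leftWidthMm,
            rotationDeg = rotationDeg, plexus = plexus, csp = csp,
            seed = seed, dgmSlice = dgmSlice, noiseSd = noiseSd))
    .phantomCache[[key]]
}

# A minimal label volume: given a list of (0-based slice -> logical matrix)
# painted with one label code, on a background of zeros.
labelVolumeFromSlices <- function(dim3, slices, code = 4L, spacing = rep(0.5, 3),
                                  orientation = "RAS") {
    arr <- array(0L, dim3)
    for (k in names(slices)) {
        m <- slices[[k]]
        arr[, , as.integer(k) + 1L][m] <- code
    }
    new("LabelVolume", labels = arr, spacing = spacing,
        orientation = orientation, labelScheme = fetaLabelScheme())
}

# Uniform-intensity volume matching a label volume's geometry.
uniformVolume <- function(labels, value = 100) {
    new("VolumeGrid", data = array(value, dim(labels@labels)),
        spacing = labels@spacing, orientation = labels@orientation)
}

planarMaskFrom <- function(mask, spacing = c(0.5, 0.5), sliceIndex = 0L,
                           axes = c(1L, 2L)) {
    new("PlanarMask", mask = mask, spacing = spacing,
        sliceIndex = as.integer(sliceIndex), axes = as.integer(axes))
}

# Rasterize a rotated solid rectangle of given side lengths (mm, including
# the one-pixel-pitch augmentation convention) into a logical matrix.
rasterRectMask <- function(longMm, shortMm, angleDeg, pitch = 0.5, pad = 8) {
    n <- ceiling((longMm + 2 * pad) / pitch)
    ctr <- (n - 1) / 2 * pitch
    coords <- (seq_len(n) - 1) * pitch
    X <- matrix(coords, n, n, byrow = TRUE)   # x along columns
    Y <- matrix(coords, n, n)                 # y along rows
    th <- angleDeg * pi / 180
    u <- (X - ctr) * cos(th) + (Y - ctr) * sin(th)
    v <- -(X - ctr) * sin(th) + (Y - ctr) * cos(th)
    abs(u) <= (longMm - pitch) / 2 & abs(v) <= (shortMm - pitch) / 2
}

# Rasterize a solid axis-aligned ellipse (semi-axes mm) rotated by angleDeg.
rasterEllipseMask <- function(majorMm, minorMm, angleDeg, pitch = 0.5, pad = 8) {
    n <- ceiling((majorMm + 2 * pad) / pitch)
    ctr <- (n - 1) / 2 * pitch
    coords <- (seq_len(n) - 1) * pitch
    X <- matrix(coords, n, n, byrow = TRUE)
    Y <- matrix(coords, n, n)
    th <- angleDeg * pi / 180
    u <- (X - ctr) * cos(th) + (Y - ctr) * sin(th)
    v <- -(X - ctr) * sin(th) + (Y - ctr) * cos(th)
    (u / (majorMm / 2))^2 + (v / (minorMm / 2))^2 < 1
}

# Brute-force minimum augmented rectangle area over a rotation grid: the
# independent oracle for the rotating-calipers implementation.
bruteMinRectArea <- function(mask, pitch, stepDeg = 0.1) {
    idx <- which(mask, arr.ind = TRUE)
    xy <- cbind((idx[, 2L] - 1) * pitch, (idx[, 1L] - 1) * pitch)
    best <- Inf
    for (deg in seq(0, 90 - stepDeg, by = stepDeg)) {
        th <- deg * pi / 180
        pu <- xy %*% c(cos(th), sin(th))
        pv <- xy %*% c(-sin(th), cos(th))
        a <- (max(pu) - min(pu) + pitch) * (max(pv) - min(pv) + pitch)
        if (a < best) best <- a
    }
    best
}

# Minor width of a rasterized shape by brute-force rotation (mm, with the
# pixel-pitch augmentation): oracle for measured widths.
bruteMinorWidth <- function(mask, pitch, stepDeg = 0.5) {
    idx <- which(mask, arr.ind = TRUE)
    xy <- cbind((idx[, 2L] - 1) * pitch, (idx[, 1L] - 1) * pitch)
    best <- c(Inf, Inf)
    for (deg in seq(0, 90 - stepDeg, by = stepDeg)) {
        th <- deg * pi / 180
        pu <- xy %*% c(cos(th), sin(th))
        pv <- xy %*% c(-sin(th), cos(th))
        a <- (max(pu) - min(pu) + pitch) * (max(pv) - min(pv) + pitch)
        if (a < best[1L])
            best <- c(a, min(max(pu) - min(pu), max(pv) - min(pv)) + pitch)
    }
    best[2L]
}

fixtureTable <- function() readMeasurementTable(bundledMeasurementTable())
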
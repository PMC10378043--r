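# Minimum-area enclosing rectangle of the true pixels of a planar mask,
# computed over the convex hull of the pixel centres. A classical rotating-
# calipers sweep over hull-edge directions yields the candidate orientations;
# because the reported side lengths are augmented by one pixel pitch (pixels
# have extent, not just centres), the minimized quantity is
# (extent1 + p) * (extent2 + p), whose optimum can sit strictly between two
# edge directions -- each angular interval is therefore refined by 1-D
# optimisation before taking the global minimum.

.rectExtents <- function(xy, theta) {
    u <- c(cos(theta), sin(theta))
    v <- c(-sin(theta), cos(theta))
    pu <- xy %*% u; pv <- xy %*% v
    list(e1 = max(pu) - min(pu), e2 = max(pv) - min(pv),
         cu = (max(pu) + min(pu)) / 2, cv = (max(pv) + min(pv)) / 2,
         u = u, v = v)
}

.degenerateRect <- function(xy, pitch) {
    ## all pixel centres (nearly) collinear: short side is one pixel pitch
    if (nrow(xy) == 1L) {
        dir <- 0
    } else {
        pc <- stats::prcomp(xy, center = TRUE)
        dir <- atan2(pc$rotation[2L, 1L], pc$rotation[1L, 1L])
    }
    ex <- .rectExtents(xy, dir)
    ctr <- ex$cu * ex$u + ex$cv * ex$v
    ang <- (dir * 180 / pi) %% 180
    if (ang >= 90) ang <- ang - 180
    new("RotatedRect",
        center = c(ctr[2L] / pitch + 1, ctr[1L] / pitch + 1),
        longSideMm = max(ex$e1 + pitch, pitch), shortSideMm = pitch,
        angleDeg = ang)
}

#' Minimum-area rectangle of a planar mask
#'
#' Returns the rotated rectangle of minimal area enclosing every true-pixel
#' centre of the mask, with side lengths in mm augmented by one pixel pitch
#' to account for pixel extent (an axis-aligned solid run of n pixels at
#' pitch p measures n*p). Degenerate (collinear) masks yield a rectangle
#' whose short side is one pixel pitch.
#'
#' @param component A non-empty \code{\linkS4class{PlanarMask}} with
#'   isotropic in-plane spacing (1\% tolerance).
#' @return A \code{\linkS4class{RotatedRect}}; \code{angleDeg} orients the
#'   long side, measured from the column direction, in [-90, 90).
#' @export
minAreaRect <- function(component) {
    stopifnot(is(component, "PlanarMask"))
    if (!any(component@mask)) stop("minAreaRect: empty mask")
    pitch <- .isotropicPitch(component@spacing, "minAreaRect")
    idx <- which(component@mask, arr.ind = TRUE)
    ## x along columns, y along rows, in mm
    xy <- cbind(x = (idx[, 2L] - 1) * pitch, y = (idx[, 1L] - 1) * pitch)

    hull <- grDevices::chull(xy)
    hp <- xy[hull, , drop = FALSE]
    if (nrow(hp) < 3L) return(.degenerateRect(xy, pitch))
    area2 <- abs(sum(hp[, 1L] * hp[c(2:nrow(hp), 1L), 2L] -
                     hp[c(2:nrow(hp), 1L), 1L] * hp[, 2L]))
    if (area2 < 1e-9) return(.degenerateRect(xy, pitch))

    edges <- hp[c(2:nrow(hp), 1L), ] - hp
    angles <- atan2(edges[, 2L], edges[, 1L]) %% (pi / 2)
    cand <- sort(unique(c(angles, 0)))
    f <- function(th) {
        ex <- .rectExtents(hp, th)
        (ex$e1 + pitch) * (ex$e2 + pitch)
    }
    best <- cand[which.min(vapply(cand, f, numeric(1)))]
    bounds <- c(cand, cand[1L] + pi / 2)
    for (i in seq_len(length(bounds) - 1L)) {
        if (bounds[i + 1L] - bounds[i] < 1e-8) next
        op <- stats::optimize(f, c(bounds[i], bounds[i + 1L]))
        if (op$objective < f(best) - 1e-12) best <- op$minimum %% (pi / 2)
    }

    ex <- .rectExtents(hp, best)
    ctr <- ex$cu * ex$u + ex$cv * ex$v
    longTheta <- if (ex$e1 >= ex$e2) best else best + pi / 2
    ang <- (longTheta * 180 / pi) %% 180
    if (ang >= 90) ang <- ang - 180
    new("RotatedRect",
        center = c(ctr[2L] / pitch + 1, ctr[1L] / pitch + 1),
        longSideMm = max(ex$e1, ex$e2) + pitch,
        shortSideMm = min(ex$e1, ex$e2) + pitch,
        angleDeg = ang)
}
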
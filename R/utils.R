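# Internal geometry/array helpers shared across modules.

.AX_LETTERS <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
.AX_POSITIVE <- c(R = TRUE, L = FALSE, A = TRUE, P = FALSE, S = TRUE, I = FALSE)

# Parse a 3-letter orientation code. For each anatomical pair returns the
# array axis it lives on and whether increasing index points to the positive
# member (right / anterior / superior).
.axisInfo <- function(orientation) {
    if (!is.character(orientation) || length(orientation) != 1L ||
        nchar(orientation) != 3L)
        stop("orientation must be a single 3-letter code such as 'RAS'")
    letters3 <- strsplit(toupper(orientation), "")[[1L]]
    if (!all(letters3 %in% names(.AX_LETTERS)))
        stop(sprintf("orientation '%s' contains letters outside RLAPSI", orientation))
    pairs <- .AX_LETTERS[letters3]
    if (anyDuplicated(pairs))
        stop(sprintf("orientation '%s' does not name three distinct anatomical axes",
                     orientation))
    list(
        lrAxis = unname(which(pairs == 1L)),
        apAxis = unname(which(pairs == 2L)),
        siAxis = unname(which(pairs == 3L)),
        lrPositiveIsRight    = unname(.AX_POSITIVE[letters3[pairs == 1L]]),
        apPositiveIsAnterior = unname(.AX_POSITIVE[letters3[pairs == 2L]]),
        siPositiveIsSuperior = unname(.AX_POSITIVE[letters3[pairs == 3L]])
    )
}

# Extract the 2D slice of a 3D array perpendicular to axis `axis` at 0-based
# index `index0`. Rows/cols of the result are the remaining axes in ascending
# order.
.extractSlice <- function(arr, axis, index0) {
    i <- index0 + 1L
    switch(axis,
        `1` = arr[i, , , drop = TRUE],
        `2` = arr[, i, , drop = TRUE],
        `3` = arr[, , i, drop = TRUE],
        stop("axis must be 1, 2 or 3"))
}

# 8-connected labeling of a logical matrix by frontier BFS. Returns an
# integer matrix: 0 = background, 1..n = component ids (arbitrary order).
.labelComponents8 <- function(mask) {
    stopifnot(is.logical(mask), is.matrix(mask))
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    todo <- which(mask)
    if (!length(todo)) return(lab)
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    comp <- 0L
    for (s in todo) {
        if (lab[s] != 0L) next
        comp <- comp + 1L
        lab[s] <- comp
        frontier <- s
        while (length(frontier)) {
            r0 <- ((frontier - 1L) %% nr) + 1L
            c0 <- ((frontier - 1L) %/% nr) + 1L
            rr <- rep(r0, times = 8L) + rep(dr, each = length(frontier))
            cc <- rep(c0, times = 8L) + rep(dc, each = length(frontier))
            ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
            lin <- (cc[ok] - 1L) * nr + rr[ok]
            lin <- unique(lin[mask[lin] & lab[lin] == 0L])
            lab[lin] <- comp
            frontier <- lin
        }
    }
    lab
}

# Largest 8-connected component of a logical matrix (ties: first label found,
# i.e. the one containing the lowest linear index). All-FALSE input returns
# the input unchanged.
.largestComponent8 <- function(mask) {
    lab <- .labelComponents8(mask)
    if (!any(lab > 0L)) return(mask)
    sizes <- tabulate(lab)
    lab == which.max(sizes)
}

#' Round half away from zero
#'
#' Display convention for reported widths and summary statistics
#' (\code{base::round} rounds half to even).
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @export
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# A single scalar in-plane pitch; errors if the two in-plane spacings differ
# by more than 1% (a scalar width in mm is otherwise ill-defined).
.isotropicPitch <- function(spacing2, context = "measurement") {
    if (abs(spacing2[1L] - spacing2[2L]) > 0.01 * max(spacing2))
        stop(sprintf("%s: in-plane spacing is anisotropic (%.4f vs %.4f mm)",
                     context, spacing2[1L], spacing2[2L]))
    mean(spacing2)
}

# Centroid (row, col) of a logical matrix.
.maskCentroid <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    colMeans(idx)
}
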
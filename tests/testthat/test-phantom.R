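test_that("identical spec and seed give bit-identical phantoms", {
    a <- makePhantom(phantomSpec(seed = 9L))
    b <- makePhantom(phantomSpec(seed = 9L))
    expect_identical(a$labels@labels, b$labels@labels)
    expect_identical(a$intensity@data, b$intensity@data)
    c <- makePhantom(phantomSpec(seed = 10L))
    expect_false(identical(a$intensity@data, c$intensity@data))
})

test_that("axis-aligned ventricles voxelize to exactly round(width/pitch) pixels", {
    ## scan the emitted label array: at zero rotation the widest left-right
    ## run of each ventricle must have exactly n pixel columns
    for (w in c(6, 7.5, 9, 12)) {
        ph <- phantomFixture(rightWidthMm = w, leftWidthMm = w,
                             rotationDeg = 0, plexus = FALSE, csp = FALSE)
        sl <- ph$labels@labels[, , ph$truth@referenceSlice + 1L] == 4L
        n <- round(w / 0.5)
        rightHalf <- sl; rightHalf[seq_len(nrow(sl) %/% 2), ] <- FALSE
        runs <- apply(rightHalf, 2, sum)          # pixels per anterior-posterior row
        expect_identical(max(runs), as.integer(n))
        expect_equal(ph$truth@rightWidthMm, n * 0.5)
    }
})

test_that("realized width is rotation-invariant to within one voxel", {
    ## brute-force minor-width oracle over the rasterized right ventricle
    widths <- vapply(c(0, 30, 60, 89), function(rot) {
        ph <- phantomFixture(rightWidthMm = 9, leftWidthMm = 9,
                             rotationDeg = rot, plexus = FALSE, csp = FALSE)
        sl <- ph$labels@labels[, , ph$truth@referenceSlice + 1L] == 4L
        sl[seq_len(nrow(sl) %/% 2), ] <- FALSE    # keep the +x (right) ventricle
        bruteMinorWidth(sl, 0.5)
    }, numeric(1))
    expect_lte(max(widths) - min(widths), 0.5 + 1e-9)
    expect_lte(max(abs(widths - 9)), 0.5 + 1e-9)
})

test_that("component count on the reference slice follows the CSP flag", {
    expect_identical(phantomFixture(csp = TRUE)$truth@componentCountOnSlice, 3L)
    expect_identical(phantomFixture(csp = FALSE)$truth@componentCountOnSlice, 2L)
})

test_that("the embedded plexus is dark and inside its ventricle", {
    ph <- phantomFixture(rightWidthMm = 12, leftWidthMm = 8, rotationDeg = 30)
    k <- ph$truth@referenceSlice
    sl <- ph$labels@labels[, , k + 1L]
    for (ctr in ph$truth@plexusCentroids) {
        expect_identical(ctr[3L], k)
        expect_identical(sl[ctr[1L] + 1L, ctr[2L] + 1L], 4L)
        vox <- ph$intensity@data[ctr[1L] + 1L, ctr[2L] + 1L, ctr[3L] + 1L]
        ventMean <- mean(ph$intensity@data[, , k + 1L][sl == 4L])
        expect_lte(vox, 0.5 * ventMean)
    }
})

test_that("phantom DGM peak matches the requested reference slice", {
    for (dgm in c(20L, 32L, 40L)) {
        ph <- phantomFixture(dgmSlice = dgm)
        expect_identical(dgmPeakSlice(ph$labels), dgm)
        expect_identical(ph$truth@referenceSlice, dgm)
    }
    ## single-slice DGM: that slice
    lv <- labelVolumeFromSlices(c(8, 8, 8),
        list("5" = matrix(TRUE, 8, 8)), code = 6L)
    expect_identical(dgmPeakSlice(lv), 5L)
    ## no DGM at all
    lv0 <- labelVolumeFromSlices(c(8, 8, 8), list(), code = 6L)
    expect_error(dgmPeakSlice(lv0), "no DGM")
})

test_that("impossible geometry is rejected", {
    expect_error(phantomSpec(rightWidthMm = 25, ventricleLengthMm = 20),
                 "smaller than")
    expect_error(phantomSpec(rightWidthMm = 0.5), "2 in-plane voxels")
    expect_error(phantomSpec(dgmSlice = 99L), "z range")
    expect_error(makePhantom(phantomSpec(shape = c(40L, 40L, 64L))), "fit")
})
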
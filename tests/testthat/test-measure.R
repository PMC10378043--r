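test_that("an axis-aligned ellipse measures its minor diameter", {
    ## minor diameter 16 px = 8 mm, uniform intensity
    m <- rasterEllipseMask(20, 8, angleDeg = 0)
    lv <- labelVolumeFromSlices(dim3 = c(dim(m), 2), list("0" = m))
    comp <- extractComponents(lv, 0L)[[1]]
    vm <- measureWidth(uniformVolume(lv, 100), comp, mode = "minrect")
    expect_lt(abs(vm@widthMm - 8), 0.5)
    expect_identical(vm@method, "minrect")
    expect_equal(vm@widthMm, vm@rect@shortSideMm)
    expect_false(vm@plexusDetected)
})

test_that("a rotated ellipse measures the same width", {
    m <- rasterEllipseMask(20, 8, angleDeg = 25)
    lv <- labelVolumeFromSlices(dim3 = c(dim(m), 2), list("0" = m))
    comp <- extractComponents(lv, 0L)[[1]]
    vm <- measureWidth(uniformVolume(lv, 100), comp)
    expect_lt(abs(vm@widthMm - 8), 1.0)
})

test_that("measured width is stable across in-plane rotations", {
    widths <- vapply(c(0, 15, 30, 60, 89), function(rot) {
        m <- rasterEllipseMask(20, 9, angleDeg = rot)
        lv <- labelVolumeFromSlices(dim3 = c(dim(m), 2), list("0" = m))
        comp <- extractComponents(lv, 0L)[[1]]
        measureWidth(uniformVolume(lv, 100), comp)@widthMm
    }, numeric(1))
    expect_lte(max(widths) - min(widths), 2 * 0.5 + 1e-9)
})

test_that("auto mode measures at the plexus margin when one is detected", {
    ph <- phantomFixture(rightWidthMm = 12, leftWidthMm = 12)
    lat <- assignLaterality(extractComponents(ph$labels,
                                              ph$truth@referenceSlice), "RAS")
    vm <- measureWidth(ph$intensity, lat$right, mode = "auto",
                       orientation = "RAS", side = "right")
    expect_true(vm@plexusDetected)
    expect_identical(vm@method, "plexus_margin")
    expect_lte(abs(vm@widthMm - 12), 1.0)
    expect_lte(vm@widthMm, vm@rect@longSideMm)

    ## without a removed cluster, auto falls back to the rectangle width
    mU <- matrix(FALSE, 30, 30); mU[10:20, 5:25] <- TRUE
    lvU <- labelVolumeFromSlices(c(30, 30, 2), list("0" = mU))
    compU <- extractComponents(lvU, 0L)[[1]]
    vmU <- measureWidth(uniformVolume(lvU, 100), compU, mode = "auto")
    expect_identical(vmU@method, "minrect")
})

test_that("full-case measurement recovers phantom widths and laterality", {
    ph <- phantomFixture(rightWidthMm = 6, leftWidthMm = 6)
    m <- measureCase(ph$intensity, ph$labels)
    expect_lt(abs(m$right@widthMm - 6), 1.0)
    expect_lt(abs(m$left@widthMm - 6), 1.0)
    expect_identical(m$right@sliceIndex, ph$truth@referenceSlice)
    expect_identical(m$left@sliceIndex, m$right@sliceIndex)

    ph2 <- phantomFixture(rightWidthMm = 12, leftWidthMm = 8)
    m2 <- measureCase(ph2$intensity, ph2$labels)
    expect_lt(abs(m2$right@widthMm - 12), 1.0)
    expect_lt(abs(m2$left@widthMm - 8), 1.0)
})

test_that("pipeline errors name their stage", {
    ph <- phantomFixture()
    noVent <- ph$labels@labels
    noVent[noVent == 4L] <- 0L
    lv <- new("LabelVolume", labels = noVent, spacing = ph$labels@spacing,
              orientation = "RAS", labelScheme = fetaLabelScheme())
    expect_error(measureCase(ph$intensity, lv), "component extraction")

    noDgm <- ph$labels@labels
    noDgm[noDgm == 6L] <- 3L
    lv2 <- new("LabelVolume", labels = noDgm, spacing = ph$labels@spacing,
               orientation = "RAS", labelScheme = fetaLabelScheme())
    expect_error(measureCase(ph$intensity, lv2), "reference slice selection")

    small <- new("VolumeGrid", data = array(0, c(4, 4, 4)),
                 spacing = rep(0.5, 3), orientation = "RAS")
    expect_error(measureCase(small, ph$labels), "different shapes")
})
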
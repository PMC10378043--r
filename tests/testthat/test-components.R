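test_that("component extraction uses 8-connectivity and sorts by area", {
    m <- matrix(FALSE, 20, 20)
    m[2:6, 2:6] <- TRUE       # 25 px
    m[10:14, 10:14] <- TRUE   # 25 px, disjoint
    lv <- labelVolumeFromSlices(c(20, 20, 4), list("1" = m))
    comps <- extractComponents(lv, 1L)
    expect_length(comps, 2L)
    expect_equal(vapply(comps, function(p) sum(p@mask), numeric(1)), c(25, 25))
    expect_identical(comps[[1]]@sliceIndex, 1L)

    ## squares touching only at a corner merge under 8-connectivity
    m2 <- matrix(FALSE, 10, 10)
    m2[1:3, 1:3] <- TRUE
    m2[4:6, 4:6] <- TRUE
    lv2 <- labelVolumeFromSlices(c(10, 10, 2), list("0" = m2))
    expect_length(extractComponents(lv2, 0L), 1L)

    ## speckle below the area floor is discarded with a message
    m3 <- matrix(FALSE, 20, 20)
    m3[2:6, 2:6] <- TRUE
    m3[15:16, 15] <- TRUE      # 2 px
    lv3 <- labelVolumeFromSlices(c(20, 20, 2), list("0" = m3))
    expect_message(comps3 <- extractComponents(lv3, 0L), "discarded")
    expect_length(comps3, 1L)

    ## empty slice errors with the stage name
    lv4 <- labelVolumeFromSlices(c(10, 10, 2), list())
    expect_error(extractComponents(lv4, 0L), "no ventricle on reference slice")
})

test_that("laterality follows the orientation code", {
    ph <- phantomFixture(rightWidthMm = 12, leftWidthMm = 8)
    comps <- extractComponents(ph$labels, ph$truth@referenceSlice)
    expect_length(comps, 3L)
    lat <- assignLaterality(comps, axisCode(ph$labels))
    ## under RAS, subject right is at larger first-axis index
    nr <- nrow(lat$right@mask)
    expect_gt(mean(which(lat$right@mask, arr.ind = TRUE)[, 1]), nr / 2)
    expect_lt(mean(which(lat$left@mask, arr.ind = TRUE)[, 1]), nr / 2)
    ## the 12 mm ventricle is the right one (larger area)
    expect_gt(sum(lat$right@mask), sum(lat$left@mask))
    ## the midline component is recognized as the septal cavity
    expect_false(is.null(lat$csp))
    mid <- mean(which(lat$csp@mask, arr.ind = TRUE)[, 1])
    expect_lt(abs(mid - (nr + 1) / 2), 4)
})

test_that("mirror-flipping the volume swaps left and right", {
    ph <- phantomFixture(rightWidthMm = 12, leftWidthMm = 8)
    arr <- ph$labels@labels
    flipped <- arr[dim(arr)[1]:1, , ]
    lvF <- new("LabelVolume", labels = flipped, spacing = ph$labels@spacing,
               orientation = "RAS", labelScheme = fetaLabelScheme())
    latF <- assignLaterality(extractComponents(lvF, ph$truth@referenceSlice),
                             "RAS")
    lat <- assignLaterality(extractComponents(ph$labels,
                                              ph$truth@referenceSlice), "RAS")
    expect_equal(sum(latF$right@mask), sum(lat$left@mask))
    expect_equal(sum(latF$left@mask), sum(lat$right@mask))
})

test_that("degenerate component configurations are reported", {
    m <- matrix(FALSE, 12, 12); m[3:7, 3:7] <- TRUE
    lv <- labelVolumeFromSlices(c(12, 12, 2), list("0" = m))
    expect_error(assignLaterality(extractComponents(lv, 0L), "RAS"),
                 "cannot separate ventricles")

    ## both components on the same side: warn, assign by relative position
    m2 <- matrix(FALSE, 40, 12)
    m2[30:33, 2:5] <- TRUE
    m2[36:39, 2:5] <- TRUE
    lv2 <- labelVolumeFromSlices(c(40, 12, 2), list("0" = m2))
    expect_warning(lat <- assignLaterality(extractComponents(lv2, 0L), "RAS"),
                   "same side")
    expect_gt(mean(which(lat$right@mask, arr.ind = TRUE)[, 1]),
              mean(which(lat$left@mask, arr.ind = TRUE)[, 1]))
})
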
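test_that("mean absolute difference: arithmetic and fixture values", {
    expect_equal(meanAbsDiff(c(1, 2), c(2, 4)), 1.5)
    expect_equal(meanAbsDiff(1:5, 1:5), 0)
    tab <- fixtureTable()
    ## published per-side error means
    expect_equal(roundHalfUp(meanAbsDiff(tab$gen_right, tab$neuro_right)), 0.55)
    expect_equal(roundHalfUp(meanAbsDiff(tab$gen_left, tab$neuro_left)), 0.48)
    expect_equal(roundHalfUp(meanAbsDiff(tab$gen_right, tab$ai_right)), 0.77)
    expect_equal(roundHalfUp(meanAbsDiff(tab$gen_left, tab$ai_left)), 1.03)
    expect_equal(roundHalfUp(meanAbsDiff(tab$neuro_right, tab$ai_right)), 0.54)
    expect_equal(roundHalfUp(meanAbsDiff(tab$neuro_left, tab$ai_left)), 1.14)
    ## exchange symmetry
    expect_equal(meanAbsDiff(tab$gen_right, tab$ai_right),
                 meanAbsDiff(tab$ai_right, tab$gen_right))
    expect_error(meanAbsDiff(1:3, 1:4), "length mismatch")
})

test_that("squared Pearson correlation behaves and hits the published values", {
    a <- c(1, 3, 4, 7, 9)
    expect_equal(pearsonR2(a, 2 * a + 3), 1.0)
    expect_equal(pearsonR2(a, rev(a)), pearsonR2(rev(a), a))
    ## invariance under positive affine transforms
    b <- c(2, 1, 5, 4, 8)
    expect_equal(pearsonR2(a, b), pearsonR2(3 * a + 1, 0.5 * b + 7))
    expect_error(pearsonR2(a, rep(2, 5)), "constant")
    expect_error(pearsonR2(1:2, 2:3), "at least 3")

    tab <- fixtureTable()
    expect_equal(pearsonR2(tab$gen_right, tab$ai_right), 0.948159231,
                 tolerance = 1e-8)
    expect_equal(pearsonR2(tab$neuro_right, tab$ai_right), 0.964945795,
                 tolerance = 1e-8)
})

test_that("paired t-test matches the closed form and handles degeneracy", {
    ## closed form: d = (1..5), t = mean/ (sd/sqrt(5)) = 3/sqrt(0.5)
    res <- pairedTTest(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, 0))
    expect_equal(res$t, sqrt(5) * 3 / sqrt(2.5), tolerance = 1e-9)
    expect_lt(abs(res$p - 0.0132), 1e-3)
    expect_identical(res$df, 4L)

    idem <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(idem$t, 0)
    expect_equal(idem$p, 1)

    expect_error(pairedTTest(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 "zero-variance differences")
    expect_error(pairedTTest(1, 2), "at least 2")
})

test_that("sample SD uses the n-1 denominator", {
    expect_equal(sampleSD(c(1, 1, 1)), 0)
    expect_equal(sampleSD(c(0, 2)), sqrt(2))
    expect_error(sampleSD(1), "at least 2")
    tab <- fixtureTable()
    ## the published table prints 1.29 here; recomputation gives 1.2991,
    ## i.e. 1.30 at two decimals (see the documented inconsistencies)
    expect_equal(roundHalfUp(sampleSD(tab$gen_right[tab$group == "normal"])),
                 1.30)
})

test_that("threshold agreement counts strictly-below-epsilon pairs", {
    expect_equal(thresholdAgreement(1:5, 1:5), c(within = 5, total = 5))
    expect_equal(thresholdAgreement(0, 1.7), c(within = 0, total = 1))
    tab <- fixtureTable()
    ## pooled neuroradiologist vs AI: one pair differs by exactly 1.7 on
    ## paper, which computes to just under 1.7 in double arithmetic (8.7 - 7)
    agr <- thresholdAgreement(c(tab$neuro_right, tab$neuro_left),
                              c(tab$ai_right, tab$ai_left))
    expect_equal(agr, c(within = 40, total = 44))
})

test_that("the full report reproduces the published comparison table", {
    tab <- fixtureTable()
    rep <- buildAgreementReport(tab,
        pairs = list(c("gen", "neuro"), c("gen", "ai"), c("neuro", "ai")))
    ps <- rep@pairStats
    expect_identical(nrow(ps), 3L)
    expect_equal(roundHalfUp(ps$mad_pooled_mm), c(0.51, 0.90, 0.84))

    ## pooled MAD identity
    expect_equal(ps$mad_pooled_mm * 44,
                 ps$mad_right_mm * 22 + ps$mad_left_mm * 22)

    ## per-case absolute differences, bit-equal to the published table
    ## after rounding to one decimal (columns: gen-neuro R/L, gen-ai R/L,
    ## neuro-ai R/L)
    published <- matrix(c(
        0.4, 1.6, 0.6, 0.9, 0.2, 0.7,
        0.9, 0.2, 0.9, 1.5, 0.0, 1.7,
        0.4, 0.5, 0.2, 1.1, 0.2, 1.6,
        1.0, 0.2, 0.5, 0.9, 1.5, 1.1,
        0.5, 0.5, 0.5, 0.3, 0.0, 0.8,
        0.5, 0.6, 0.9, 1.2, 0.4, 0.6,
        1.3, 0.3, 0.9, 0.1, 0.4, 0.2,
        0.3, 0.2, 0.9, 1.4, 0.6, 1.6,
        0.3, 0.8, 0.4, 0.2, 0.1, 0.6,
        0.1, 0.2, 1.5, 0.5, 1.4, 0.7,
        0.1, 0.4, 0.7, 3.2, 0.8, 3.6,
        0.9, 0.5, 1.3, 0.3, 0.4, 0.8,
        0.8, 0.6, 0.7, 0.8, 0.1, 1.4,
        1.0, 0.5, 1.3, 0.6, 0.3, 0.1,
        0.5, 0.4, 0.1, 1.0, 0.4, 1.4,
        0.1, 0.0, 0.8, 1.0, 0.7, 1.0,
        0.4, 0.3, 0.0, 0.3, 0.4, 0.0,
        0.4, 0.4, 2.9, 2.4, 2.5, 2.0,
        0.2, 1.0, 0.7, 1.1, 0.5, 2.1,
        0.4, 0.5, 0.1, 0.8, 0.5, 0.3,
        0.6, 0.6, 0.6, 2.2, 0.0, 1.6,
        0.9, 0.3, 0.5, 0.9, 0.4, 1.2), ncol = 6, byrow = TRUE)
    pairsOrder <- list(c("gen", "neuro"), c("gen", "ai"), c("neuro", "ai"))
    for (j in seq_along(pairsOrder)) {
        p <- pairsOrder[[j]]
        pc <- rep@perCase[rep@perCase$rater_a == p[1] &
                          rep@perCase$rater_b == p[2], ]
        expect_equal(roundHalfUp(pc$abs_diff_right_mm, 1),
                     published[, 2 * j - 1])
        expect_equal(roundHalfUp(pc$abs_diff_left_mm, 1),
                     published[, 2 * j])
    }

    ## degrees of freedom over the pooled 44 ventricles
    expect_true(all(ps$df == 43L))
    ## single-pair request yields exactly one block
    one <- buildAgreementReport(tab, pairs = list(c("gen", "ai")))
    expect_identical(nrow(one@pairStats), 1L)
    ## epsilon 0: nothing can be strictly within
    z <- buildAgreementReport(tab, pairs = list(c("gen", "ai")), epsilonMm = 0)
    expect_equal(z@pairStats$within_threshold, 0)
    expect_error(buildAgreementReport(tab, pairs = list(c("gen", "nobody"))),
                 "not in table")
})

test_that("report CSVs are written and round-trip their pair statistics", {
    tab <- fixtureTable()
    rep <- buildAgreementReport(tab, pairs = list(c("neuro", "ai")))
    base <- withr::local_tempfile(fileext = ".csv")
    files <- writeAgreementReport(rep, base)
    expect_true(all(file.exists(files)))
    back <- utils::read.csv(files[1])
    expect_equal(back$mad_pooled_mm, rep@pairStats$mad_pooled_mm)
    expect_equal(back$mad_pooled_display, 0.84)
})
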
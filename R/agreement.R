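#' Mean absolute difference between two width lists
#'
#' @param a,b Equal-length numeric vectors (mm).
#' @return Mean of |a - b| at full precision (render with
#'   \code{\link{roundHalfUp}} for display).
#' @export
meanAbsDiff <- function(a, b) {
    if (length(a) != length(b)) stop("meanAbsDiff: length mismatch")
    if (!length(a)) stop("meanAbsDiff: empty input")
    mean(abs(a - b))
}

#' Squared Pearson correlation
#'
#' The R-squared used to compare raters is the square of the Pearson
#' product-moment correlation between their width lists.
#'
#' @param a,b Numeric vectors of length >= 3, neither constant.
#' @return Value in [0, 1].
#' @export
pearsonR2 <- function(a, b) {
    if (length(a) != length(b)) stop("pearsonR2: length mismatch")
    if (length(a) < 3L) stop("pearsonR2: need at least 3 pairs")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("pearsonR2: undefined for constant input")
    stats::cor(a, b)^2
}

#' Paired two-sided t-test on width lists
#'
#' Student's paired t on the differences d = a - b with df = n - 1. Identical
#' lists return t = 0, p = 1; constant non-zero differences have zero
#' variance and raise an error.
#'
#' @param a,b Equal-length numeric vectors, n >= 2.
#' @return List with \code{t}, \code{p}, \code{df}.
#' @export
pairedTTest <- function(a, b) {
    if (length(a) != length(b)) stop("pairedTTest: length mismatch")
    n <- length(a)
    if (n < 2L) stop("pairedTTest: need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
        if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L))
        stop("pairedTTest: zero-variance differences")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = as.integer(round(unname(tt$parameter))))
}

#' Sample standard deviation (n - 1 denominator)
#' @param x Numeric vector of length >= 2.
#' @export
sampleSD <- function(x) {
    if (length(x) < 2L) stop("sampleSD: need at least 2 values")
    stats::sd(x)
}

#' Agreement within an error threshold
#'
#' Counts pairs whose absolute difference is strictly below
#' \code{epsilonMm}. The default threshold of 1.7 mm is the maximum error of
#' an accepted measurement in the reference reading protocol.
#'
#' @param a,b Equal-length numeric vectors (mm).
#' @param epsilonMm Error threshold in mm (default 1.7).
#' @return Named numeric: \code{within} and \code{total}.
#' @export
thresholdAgreement <- function(a, b, epsilonMm = 1.7) {
    if (length(a) != length(b)) stop("thresholdAgreement: length mismatch")
    c(within = sum(abs(a - b) < epsilonMm), total = length(a))
}

#' Normal/abnormal classification counts for one rater
#'
#' Applies \code{\link{classifyCase}} to a rater's right/left columns of a
#' measurement table and tallies the case labels.
#'
#' @param table A table from \code{\link{readMeasurementTable}}.
#' @param rater Rater prefix, e.g. \code{"gen"}, \code{"neuro"}, \code{"ai"}.
#' @param thresholdMm Ventriculomegaly threshold (default 10).
#' @return Named numeric: \code{n_normal} and \code{n_abnormal}.
#' @export
classificationCounts <- function(table, rater, thresholdMm = 10) {
    if (!rater %in% raterNames(table))
        stop(sprintf("classificationCounts: unknown rater '%s'", rater))
    if (!nrow(table)) return(c(n_normal = 0, n_abnormal = 0))
    r <- table[[paste0(rater, "_right")]]
    l <- table[[paste0(rater, "_left")]]
    labs <- mapply(function(ri, li)
        classifyCase(ri, li, thresholdMm = thresholdMm)@caseLabel, r, l)
    c(n_normal = sum(labs == "normal"),
      n_abnormal = sum(labs == "ventriculomegaly"))
}

#' Build the full rater-agreement report
#'
#' For every requested rater pair: per-side and pooled mean absolute
#' differences, per-side squared Pearson correlations, a paired two-sided t
#' over the pooled ventricles (both sides concatenated, df = 2n - 1) and the
#' within-threshold agreement count. Per-case absolute differences and
#' per-rater summary statistics (mean, sample SD) are included.
#'
#' @param table A table from \code{\link{readMeasurementTable}}.
#' @param pairs List of length-2 character vectors of rater prefixes;
#'   default: every unordered pair in the table.
#' @param epsilonMm Agreement threshold in mm (default 1.7).
#' @return An \code{\linkS4class{AgreementReport}}.
#' @export
buildAgreementReport <- function(table, pairs = NULL, epsilonMm = 1.7) {
    raters <- raterNames(table)
    if (is.null(pairs)) {
        pairs <- utils::combn(raters, 2L, simplify = FALSE)
    }
    for (p in pairs) {
        miss <- setdiff(p, raters)
        if (length(miss))
            stop(sprintf("buildAgreementReport: rater(s) not in table: %s",
                         paste(miss, collapse = ", ")))
    }
    col <- function(r, s) table[[paste0(r, "_", s)]]
    stats <- do.call(rbind, lapply(pairs, function(p) {
        ar <- col(p[1L], "right"); al <- col(p[1L], "left")
        br <- col(p[2L], "right"); bl <- col(p[2L], "left")
        tt <- pairedTTest(c(ar, al), c(br, bl))
        agr <- thresholdAgreement(c(ar, al), c(br, bl), epsilonMm)
        data.frame(rater_a = p[1L], rater_b = p[2L],
                   mad_right_mm = meanAbsDiff(ar, br),
                   mad_left_mm = meanAbsDiff(al, bl),
                   mad_pooled_mm = meanAbsDiff(c(ar, al), c(br, bl)),
                   r2_right = pearsonR2(ar, br), r2_left = pearsonR2(al, bl),
                   t_stat = tt$t, p_two_sided = tt$p, df = tt$df,
                   within_threshold = agr[["within"]], total = agr[["total"]],
                   stringsAsFactors = FALSE)
    }))
    perCase <- do.call(rbind, lapply(pairs, function(p) {
        data.frame(case_id = table$case_id, group = table$group,
                   rater_a = p[1L], rater_b = p[2L],
                   abs_diff_right_mm = abs(col(p[1L], "right") - col(p[2L], "right")),
                   abs_diff_left_mm = abs(col(p[1L], "left") - col(p[2L], "left")),
                   stringsAsFactors = FALSE)
    }))
    summary <- do.call(rbind, lapply(raters, function(r) {
        data.frame(rater = r,
                   mean_right_mm = mean(col(r, "right")),
                   sd_right_mm = sampleSD(col(r, "right")),
                   mean_left_mm = mean(col(r, "left")),
                   sd_left_mm = sampleSD(col(r, "left")),
                   stringsAsFactors = FALSE)
    }))
    new("AgreementReport", pairStats = stats, perCase = perCase,
        raterSummary = summary, epsilonMm = epsilonMm)
}

#' Write an agreement report to CSV
#'
#' Three stacked sections (pair statistics, per-case absolute differences,
#' per-rater summaries) written to one CSV each, named by suffix; values are
#' written at full precision plus a display column rounded half-up to two
#' decimals for the pooled mean absolute differences.
#'
#' @param report An \code{\linkS4class{AgreementReport}}.
#' @param path Base path; \code{_pairs.csv}, \code{_per_case.csv} and
#'   \code{_raters.csv} are appended.
#' @return Invisibly, the three file paths.
#' @export
writeAgreementReport <- function(report, path) {
    stopifnot(is(report, "AgreementReport"))
    base <- sub("\\.csv$", "", path)
    ps <- report@pairStats
    ps$mad_pooled_display <- roundHalfUp(ps$mad_pooled_mm, 2L)
    files <- paste0(base, c("_pairs.csv", "_per_case.csv", "_raters.csv"))
    utils::write.csv(ps, files[1L], row.names = FALSE)
    utils::write.csv(report@perCase, files[2L], row.names = FALSE)
    utils::write.csv(report@raterSummary, files[3L], row.names = FALSE)
    invisible(files)
}
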
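#' Grade a single ventricle width
#'
#' Clinical severity bins for ventriculomegaly: widths of at most 10 mm are
#' normal, above 10 and below 13 mm mild, 13 to 15 mm moderate, above 15 mm
#' severe. The boundary at exactly 10.0 mm is normal (the dilatation
#' criterion is strictly "wider than 10 mm"), and the published integer
#' ranges (10--12 / 13--15) leave (12, 13) unassigned, which this package
#' resolves by extending mild up to 13 mm; both choices are configurable via
#' \code{edges}.
#'
#' @param widthMm Positive width in mm.
#' @param edges Increasing numeric length-3: (normal/mild, mild/moderate,
#'   moderate/severe) boundaries, default \code{c(10, 13, 15)}.
#' @return One of \code{"normal"}, \code{"mild"}, \code{"moderate"},
#'   \code{"severe"}.
#' @export
#' @examples
#' gradeVentricle(9.9)   # normal
#' gradeVentricle(11.0)  # mild
#' gradeVentricle(14.0)  # moderate
#' gradeVentricle(16.9)  # severe
gradeVentricle <- function(widthMm, edges = c(10, 13, 15)) {
    if (!is.numeric(widthMm) || length(widthMm) != 1L || !is.finite(widthMm) ||
        widthMm <= 0)
        stop("gradeVentricle: width must be a positive number")
    if (length(edges) != 3L || any(diff(edges) <= 0))
        stop("gradeVentricle: edges must be 3 increasing numbers")
    if (widthMm <= edges[1L]) "normal"
    else if (widthMm < edges[2L]) "mild"
    else if (widthMm <= edges[3L]) "moderate"
    else "severe"
}

#' Classify a case from its two ventricle widths
#'
#' A case is ventriculomegaly when either ventricle is strictly wider than
#' the threshold (default 10 mm). For normal cases, a left--right asymmetry
#' exceeding \code{asymmetryMm} (default 2.4 mm) is flagged: asymmetry
#' without dilatation is considered a normal variant but worth reporting.
#'
#' @param rightMm,leftMm Positive widths in mm.
#' @param thresholdMm Ventriculomegaly threshold (default 10).
#' @param asymmetryMm Asymmetry allowance for normal cases (default 2.4).
#' @param edges Severity bin edges passed to \code{\link{gradeVentricle}}.
#' @return A \code{\linkS4class{CaseClassification}}.
#' @export
#' @examples
#' classifyCase(7.2, 12.7)   # ventriculomegaly
#' classifyCase(5.1, 7.9)    # normal, asymmetry 2.8 -> flagged
classifyCase <- function(rightMm, leftMm, thresholdMm = 10,
                         asymmetryMm = 2.4, edges = c(10, 13, 15)) {
    for (w in c(rightMm, leftMm))
        if (!is.numeric(w) || !is.finite(w) || w <= 0)
            stop("classifyCase: widths must be positive numbers")
    vm <- max(rightMm, leftMm) > thresholdMm
    asym <- abs(leftMm - rightMm)
    new("CaseClassification",
        rightMm = rightMm, leftMm = leftMm,
        caseLabel = if (vm) "ventriculomegaly" else "normal",
        rightGrade = gradeVentricle(rightMm, edges),
        leftGrade = gradeVentricle(leftMm, edges),
        asymmetryMm = asym,
        asymmetryFlag = !vm && asym > asymmetryMm)
}
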
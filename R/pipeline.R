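#' Construct a pipeline configuration
#'
#' Every clinical threshold used anywhere in the pipeline is sourced from
#' this object; there are no hidden constants.
#'
#' @param mode Measurement mode (\code{"minrect"}, \code{"plexus_margin"},
#'   \code{"auto"}); default \code{"minrect"}.
#' @param epsilonMm Agreement threshold in mm (default 1.7).
#' @param vmThresholdMm Ventriculomegaly threshold in mm (default 10).
#' @param severityEdgesMm Severity bin edges in mm (default 10, 13, 15).
#' @param asymmetryMm Asymmetry allowance in mm (default 2.4).
#' @param seed RNG seed for any stochastic stage (default 42).
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return A \code{\linkS4class{RunConfig}}.
#' @export
runConfig <- function(mode = "minrect", epsilonMm = 1.7, vmThresholdMm = 10,
                      severityEdgesMm = c(10, 13, 15), asymmetryMm = 2.4,
                      seed = 42L, logLevel = "info") {
    new("RunConfig", mode = mode, epsilonMm = epsilonMm,
        vmThresholdMm = vmThresholdMm, severityEdgesMm = severityEdgesMm,
        asymmetryMm = asymmetryMm, seed = as.integer(seed),
        logLevel = logLevel)
}

#' Load a pipeline configuration from file
#'
#' Reads a flat JSON or YAML file of configuration keys; absent keys take
#' their defaults and unknown keys are rejected. With \code{path = NULL} all
#' defaults are returned.
#'
#' @param path Optional path to a \code{.json}, \code{.yaml} or \code{.yml}
#'   file.
#' @return A validated \code{\linkS4class{RunConfig}}.
#' @export
loadRunConfig <- function(path = NULL) {
    if (is.null(path)) return(runConfig())
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else
        jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.list(vals)) stop("config file must contain a flat key-value object")
    known <- c("mode", "epsilonMm", "vmThresholdMm", "severityEdgesMm",
               "asymmetryMm", "seed", "logLevel")
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop(sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")))
    cfg <- tryCatch(do.call(runConfig, vals), error = function(e)
        stop(sprintf("config: %s", conditionMessage(e)), call. = FALSE))
    if (any(diff(cfg@severityEdgesMm) <= 0))
        stop("config: severityEdgesMm not increasing")
    cfg
}

#' Run the full measurement pipeline on one case
#'
#' Loads a co-registered intensity/label NIfTI pair, measures both lateral
#' ventricles and classifies the case. Upstream stages (brain extraction,
#' super-resolution reconstruction, tissue segmentation) are represented by
#' the input contract only: the label volume is required as a file. The
#' result is deterministic for a given input pair and configuration.
#'
#' @param intensityPath Path to the intensity NIfTI.
#' @param labelsPath Path to the co-registered label NIfTI.
#' @param config A \code{\linkS4class{RunConfig}}; default
#'   \code{loadRunConfig()}.
#' @param scheme Label scheme (default \code{\link{fetaLabelScheme}}).
#' @return A list ready for JSON serialization: slice index, per-side width
#'   (mm, two decimals half-up), grade, method, threshold and rectangle
#'   parameters, the case label, asymmetry, and a stage log.
#' @export
runPipeline <- function(intensityPath, labelsPath, config = loadRunConfig(),
                        scheme = fetaLabelScheme()) {
    stopifnot(is(config, "RunConfig"))
    log <- character()
    note <- function(fmt, ...) {
        msg <- sprintf(fmt, ...)
        if (config@logLevel != "quiet") message(msg)
        log <<- c(log, msg)
    }
    if (!file.exists(labelsPath))
        stop(sprintf("input: labels file not found: %s", labelsPath))
    if (!file.exists(intensityPath))
        stop(sprintf("input: intensity file not found: %s", intensityPath))
    labels <- readLabelVolume(labelsPath, scheme)
    intensity <- readVolumeGrid(intensityPath)
    note("loaded volumes %s (orientation %s)",
         paste(dim(labels@labels), collapse = "x"), axisCode(labels))

    m <- measureCase(intensity, labels, mode = config@mode)
    note("reference slice %d (DGM area %.2f mm^2)", m$slice@index,
         m$slice@dgmAreaMm2)
    note("right: %.2f mm (%s), left: %.2f mm (%s)",
         m$right@widthMm, m$right@method, m$left@widthMm, m$left@method)

    cls <- classifyCase(m$right@widthMm, m$left@widthMm,
                        thresholdMm = config@vmThresholdMm,
                        asymmetryMm = config@asymmetryMm,
                        edges = config@severityEdgesMm)
    note("case label: %s", cls@caseLabel)

    sideOut <- function(vm, grade) list(
        width_mm = roundHalfUp(vm@widthMm, 2L),
        grade = grade, method = vm@method,
        plexus_detected = vm@plexusDetected,
        threshold = vm@thresholdUsed,
        rect = list(center = as.numeric(vm@rect@center),
                    long_side_mm = vm@rect@longSideMm,
                    short_side_mm = vm@rect@shortSideMm,
                    angle_deg = vm@rect@angleDeg))
    list(slice_index = m$slice@index,
         right = sideOut(m$right, cls@rightGrade),
         left = sideOut(m$left, cls@leftGrade),
         case_label = cls@caseLabel,
         asymmetry_mm = cls@asymmetryMm,
         asymmetry_flag = cls@asymmetryFlag,
         config = list(mode = config@mode,
                       vm_threshold_mm = config@vmThresholdMm,
                       severity_edges_mm = config@severityEdgesMm,
                       asymmetry_mm = config@asymmetryMm),
         log = log)
}
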
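#' @import methods
#' @importFrom stats cor pchisq qr.resid quantile rnorm runif rbinom sd var
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Cohort container for brain-SES analyses
#'
#' `SESCohort` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay named `features` holding image-derived brain phenotypes (features in
#' rows, participants in columns). `rowData` is the atlas-metadata table
#' (`feature_id`, `name`, `hemisphere`, `tissue`, `homologue_id`); `colData`
#' carries the six raw SES indicator columns plus confound/covariate columns,
#' aligned by `participant_id`. Metadata lists the indicator and confound
#' column names and, for simulated cohorts, the ground-truth objects.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("SESCohort", contains = "SummarizedExperiment")

.validSESCohort <- function(object) {
    msg <- character(0)
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    rd <- rowData(object)
    need <- c("feature_id", "name", "hemisphere", "tissue", "homologue_id")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, paste0("rowData must contain columns: ",
                             paste(need, collapse = ", ")))
    } else {
        if (!all(rd$hemisphere %in% c("L", "R", "M")))
            msg <- c(msg, "hemisphere must be one of L, R, M")
        if (!all(rd$tissue %in% c("cortical", "subcortical", "tract")))
            msg <- c(msg, "tissue must be cortical, subcortical or tract")
        hid <- rd$homologue_id
        if (any(rd$hemisphere == "M" & !is.na(hid) & hid != ""))
            msg <- c(msg, "midline (M) features must have empty homologue_id")
        lat <- hid[rd$hemisphere != "M"]
        lat <- lat[!is.na(lat) & lat != ""]
        if (length(lat) && any(table(lat) != 2L))
            msg <- c(msg, "each homologue_id must occur exactly twice")
    }
    ind <- metadata(object)$indicators
    if (is.null(ind) || !all(ind %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain all SES indicator columns")
    if (length(msg)) msg else TRUE
}
setValidity("SESCohort", .validSESCohort)

#' Preprocessed model frame: design and outcome matrices
#'
#' Output of [preprocessCohort()]. `X` holds z-scored residualized brain
#' features followed by the z-scored covariate block; `Y` the z-scored,
#' orientation-harmonized SES indicators. Standardization and residualization
#' parameters are retained so held-out data can be transformed identically.
#'
#' @slot X numeric matrix, participants by columns (brain features then
#'   covariates), each column mean 0, sd 1 (sample convention).
#' @slot Y numeric matrix, participants by 6 indicators, standardized.
#' @slot roles character vector, one of `"brain_feature"`/`"covariate"` per
#'   column of `X`.
#' @slot xStandardization,yStandardization lists with `center` and `scale`.
#' @slot residualCoefficients nuisance-regression coefficients fitted on the
#'   analysis sample (intercept row first).
#' @export
setClass("ModelFrame", representation(
    X = "matrix", Y = "matrix", roles = "character",
    xStandardization = "list", yStandardization = "list",
    residualCoefficients = "matrix"))

.validModelFrame <- function(object) {
    msg <- character(0)
    if (nrow(object@X) != nrow(object@Y))
        msg <- c(msg, "X and Y must have the same number of rows")
    if (length(object@roles) != ncol(object@X))
        msg <- c(msg, "one role per X column required")
    if (anyNA(object@X) || anyNA(object@Y))
        msg <- c(msg, "missing values are not allowed")
    if (ncol(object@X)) {
        if (max(abs(colMeans(object@X))) > 1e-10)
            msg <- c(msg, "X columns must have mean 0 (tolerance 1e-10)")
        if (max(abs(apply(object@X, 2, sd) - 1)) > 1e-10)
            msg <- c(msg, "X columns must have sd 1 (tolerance 1e-10)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ModelFrame", .validModelFrame)

#' Multi-output ridge solution
#'
#' The p-by-k matrix of standardized slopes linking design columns to the SES
#' indicators, with the regularization strength and solver that produced it.
#'
#' @slot coefficients p-by-k numeric matrix (features/covariates by
#'   indicators).
#' @slot alpha non-negative l2 penalty strength.
#' @slot solver `"closed_form"` or `"coordinate_descent"`.
#' @slot iterations sweeps used (0 for the closed form).
#' @export
setClass("RidgeSolution", representation(
    coefficients = "matrix", alpha = "numeric", solver = "character",
    iterations = "integer"))

setValidity("RidgeSolution", function(object) {
    if (!all(is.finite(object@coefficients)))
        return("coefficients must be finite")
    if (object@alpha < 0) return("alpha must be >= 0")
    TRUE
})

#' Bootstrap-bagged coefficient ensemble
#'
#' Summary of refitting the full model on `B` with-replacement participant
#' resamples: elementwise ensemble mean, standard deviation and 5%/95%
#' percentile bounds, plus the raw draws.
#'
#' @slot mean,sd,lo5,hi95 p-by-k matrices summarizing the ensemble.
#' @slot draws B-by-p-by-k array of refitted coefficients.
#' @slot B resample count.
#' @slot seed RNG seed used.
#' @slot redraws number of degenerate resamples that were redrawn.
#' @export
setClass("BaggedSolution", representation(
    mean = "matrix", sd = "matrix", lo5 = "matrix", hi95 = "matrix",
    draws = "array", B = "integer", seed = "integer", redraws = "integer"))

setValidity("BaggedSolution", function(object) {
    if (object@B < 2L) return("B must be >= 2 for interval formation")
    if (!all(object@lo5 <= object@hi95 + 1e-12))
        return("lo5 must not exceed hi95")
    TRUE
})

#' Permutation max-statistic null distribution
#'
#' Per permutation, the outcome rows are shuffled as a block (all six
#' indicators move together, the design matrix held fixed), the model is
#' refit, and the maximum absolute coefficient over all p-by-k cells is
#' recorded.
#'
#' @slot maxStats R-vector of per-permutation maxima.
#' @slot R permutation count.
#' @slot seed RNG seed used.
#' @slot mode `"plain_fit"` or `"bagged_fit"` null statistic.
#' @slot cellStats optional R-by-(p*k) matrix of per-cell absolute null
#'   statistics (kept only on request; used for diagnostics).
#' @export
setClass("PermutationNull", representation(
    maxStats = "numeric", R = "integer", seed = "integer", mode = "character",
    cellStats = "matrix"))

setValidity("PermutationNull", function(object) {
    if (object@R < 1L) return("R must be >= 1")
    if (length(object@maxStats) != object@R)
        return("maxStats length must equal R")
    TRUE
})

#' Family-wise-error significance report
#'
#' Permutation FWE-corrected p-values and significance flags for every
#' (feature, indicator) cell, using the add-one counting convention
#' p = (1 + #\{null maxima >= |observed|\}) / (1 + R).
#'
#' @slot pFWE p-by-k matrix of corrected p-values in (0, 1].
#' @slot significant logical p-by-k matrix, `pFWE < threshold`.
#' @slot threshold significance threshold (default 0.001).
#' @slot R permutation count behind the p-values.
#' @export
setClass("SignificanceReport", representation(
    pFWE = "matrix", significant = "matrix", threshold = "numeric",
    R = "integer"))

setValidity("SignificanceReport", function(object) {
    if (any(object@pFWE <= 0) || any(object@pFWE > 1))
        return("pFWE must lie in (0, 1]")
    if (!identical(dim(object@pFWE), dim(object@significant)))
        return("pFWE and significant must have identical shape")
    TRUE
})
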
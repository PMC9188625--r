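#' Default orientation map for the six SES indicators
#'
#' After orientation a larger value means higher SES for every indicator.
#' Only the neighborhood indicator (a deprivation index) is inverted; the
#' binary job indicator is coded 1 = knowledge worker ("white collar"),
#' 0 = manual worker ("blue collar").
#'
#' @return data.frame with columns `indicator`, `direction`
#'   (`"as-is"`/`"invert"`) and `encoding`.
#' @export
defaultOrientationMap <- function() {
    data.frame(
        indicator = .INDICATORS,
        direction = c("as-is", "as-is", "as-is", "invert", "as-is", "as-is"),
        encoding = c("ordinal", "continuous", "ordinal", "continuous",
                     "ordinal", "binary"),
        stringsAsFactors = FALSE)
}

#' Harmonize indicator orientation
#'
#' Applies the per-indicator direction so that larger values always mean
#' higher SES (inversion is a sign flip, preserving all rank information).
#'
#' @param rawSes data.frame or matrix with all six indicator columns.
#' @param map orientation map as from [defaultOrientationMap()].
#' @return data.frame with columns in map order, inverted where requested.
#' @export
orientIndicators <- function(rawSes, map = defaultOrientationMap()) {
    rawSes <- as.data.frame(rawSes)
    missing <- setdiff(map$indicator, colnames(rawSes))
    if (length(missing))
        stop("unknown/missing indicator id(s): ",
             paste(missing, collapse = ", "))
    out <- rawSes[, map$indicator, drop = FALSE]
    for (i in seq_len(nrow(map))) {
        col <- map$indicator[i]
        if (!is.numeric(out[[col]]))
            stop("non-numeric entries in indicator: ", col)
        if (map$direction[i] == "invert") out[[col]] <- -out[[col]]
    }
    out
}

#' Residualize features on nuisance variables
#'
#' Removes, by least squares with an intercept, all linear variation in each
#' feature column that head size, BMI or any other nuisance column can
#' explain. When `coefficients` is supplied the stored fit is applied instead
#' of refitting (for held-out data).
#'
#' @param features numeric matrix (participants by features).
#' @param nuisance numeric matrix of nuisance columns, aligned rows.
#' @param coefficients optional coefficient matrix from a previous fit
#'   (intercept row first), as stored in the `"coefficients"` attribute of a
#'   previous result.
#' @return residual matrix with attribute `"coefficients"`.
#' @export
residualize <- function(features, nuisance, coefficients = NULL) {
    features <- as.matrix(features)
    nuisance <- as.matrix(nuisance)
    if (nrow(features) != nrow(nuisance))
        stop("row count mismatch between features and nuisance")
    if (is.null(colnames(nuisance)))
        colnames(nuisance) <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
    Z <- cbind(`(Intercept)` = 1, nuisance)
    if (is.null(coefficients)) {
        qz <- qr(Z)
        if (qz$rank < ncol(Z)) {
            bad <- colnames(Z)[qz$pivot[seq(qz$rank + 1L, ncol(Z))]]
            stop("rank-deficient nuisance matrix; offending column(s): ",
                 paste(bad, collapse = ", "))
        }
        coefficients <- qr.coef(qz, features)
    }
    res <- features - Z %*% coefficients
    dimnames(res) <- dimnames(features)
    attr(res, "coefficients") <- coefficients
    res
}

#' Build the covariate block
#'
#' Columns in fixed order: age, sex, age^2, age*sex, age^2*sex, fluid IQ and
#' optionally handedness. Age is centered (default: at its own mean) before
#' powers and interactions are formed, which reduces collinearity without
#' changing the fitted subspace. Constant columns (e.g. when age does not
#' vary) are flagged in the `"constant"` attribute for removal before
#' standardization.
#'
#' @param age,sex,iq aligned numeric vectors; sex coded 0/1.
#' @param handedness optional aligned 0/1 vector.
#' @param ageCenter value to center age at; supply the training-set mean when
#'   transforming held-out data.
#' @return numeric matrix with attribute `"constant"` (names of degenerate
#'   columns) and `"ageCenter"`.
#' @export
buildCovariates <- function(age, sex, iq, handedness = NULL,
                            ageCenter = mean(age)) {
    if (missing(age) || missing(sex) || missing(iq))
        stop("age, sex and iq are required")
    n <- length(age)
    if (length(sex) != n || length(iq) != n)
        stop("covariate vectors must be aligned (equal length)")
    if (!all(sex %in% c(0, 1))) stop("sex must be coded {0,1}")
    a <- age - ageCenter
    M <- cbind(age = a, sex = sex, age2 = a^2, age_sex = a * sex,
               age2_sex = a^2 * sex, iq = iq)
    if (!is.null(handedness)) {
        if (length(handedness) != n) stop("handedness length mismatch")
        M <- cbind(M, handedness = handedness)
    }
    sds <- apply(M, 2, sd)
    attr(M, "constant") <- colnames(M)[sds < 1e-12]
    attr(M, "ageCenter") <- ageCenter
    M
}

#' Z-score columns and record the transformation
#'
#' De-means each column to zero average and scales to unit variance using the
#' sample (n-1) standard-deviation convention. The recorded parameters allow
#' identical transformation of held-out data via [applyStandardization()].
#'
#' @param m numeric matrix.
#' @return list with `values` (z-scored matrix), `center` and `scale`.
#' @export
standardize <- function(m) {
    m <- as.matrix(m)
    ctr <- colMeans(m)
    scl <- apply(m, 2, sd)
    if (any(scl <= 1e-12)) {
        bad <- colnames(m)[scl <= 1e-12]
        if (is.null(bad)) bad <- which(scl <= 1e-12)
        stop("constant column(s) cannot be standardized: ",
             paste(bad, collapse = ", "))
    }
    vals <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
    list(values = vals, center = ctr, scale = scl)
}

#' @rdname standardize
#' @param params list with `center` and `scale` from a previous
#'   [standardize()] call.
#' @export
applyStandardization <- function(m, params) {
    m <- as.matrix(m)
    sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
}

#' Drop rows with any missing value
#'
#' The modeling pipeline requires complete cases; this utility removes
#' incomplete participants and reports how many were dropped.
#'
#' @param ... matrices/data.frames with aligned rows.
#' @return list of the inputs restricted to jointly complete rows, with
#'   attribute `"nDropped"`.
#' @export
dropIncompleteRows <- function(...) {
    tabs <- list(...)
    ok <- Reduce(`&`, lapply(tabs, function(t) stats::complete.cases(t)))
    nd <- sum(!ok)
    if (nd > 0L)
        message("dropIncompleteRows: removed ", nd, " incomplete row(s)")
    out <- lapply(tabs, function(t) t[ok, , drop = FALSE])
    attr(out, "nDropped") <- nd
    out
}

#' Preprocess a cohort into design and outcome matrices
#'
#' Runs the full preparatory chain: indicator orientation, residualization of
#' brain features on the nuisance confounds (head size and BMI by default),
#' covariate-block construction (dropping degenerate columns), and z-scoring
#' of every design and outcome column. The covariate block is appended after
#' the brain features and penalized together with them downstream.
#'
#' @param cohort an [SESCohort-class].
#' @param orientation orientation map, see [defaultOrientationMap()].
#' @param includeHandedness include handedness as an extra covariate.
#' @param nuisance confound columns to residualize the brain features on.
#' @return a [ModelFrame-class].
#' @export
preprocessCohort <- function(cohort, orientation = defaultOrientationMap(),
                             includeHandedness = FALSE,
                             nuisance = c("head_size", "bmi")) {
    feats <- brainFeatures(cohort)
    conf <- confoundTable(cohort)
    missingNuis <- setdiff(nuisance, colnames(conf))
    if (length(missingNuis))
        stop("nuisance column(s) absent from cohort: ",
             paste(missingNuis, collapse = ", "))
    res <- residualize(feats, as.matrix(conf[, nuisance, drop = FALSE]))
    cov <- buildCovariates(
        age = conf$age, sex = conf$sex, iq = conf$iq,
        handedness = if (includeHandedness) conf$handedness else NULL)
    keep <- setdiff(colnames(cov), attr(cov, "constant"))
    cov <- cov[, keep, drop = FALSE]

    Xraw <- cbind(res, cov)
    sx <- standardize(Xraw)
    Yor <- as.matrix(orientIndicators(sesTable(cohort), orientation))
    sy <- standardize(Yor)
    new("ModelFrame",
        X = sx$values, Y = sy$values,
        roles = c(rep("brain_feature", ncol(res)),
                  rep("covariate", ncol(cov))),
        xStandardization = list(center = sx$center, scale = sx$scale),
        yStandardization = list(center = sy$center, scale = sy$scale),
        residualCoefficients = attr(res, "coefficients"))
}

#' Accessors for ModelFrame components
#'
#' @param x a [ModelFrame-class].
#' @return `designMatrix()` the standardized design matrix X,
#'   `outcomeMatrix()` the standardized outcome matrix Y, `columnRoles()` the
#'   per-column role vector.
#' @export
designMatrix <- function(x) x@X

#' @rdname designMatrix
#' @export
outcomeMatrix <- function(x) x@Y

#' @rdname designMatrix
#' @export
columnRoles <- function(x) x@roles

setMethod("show", "ModelFrame", function(object) {
    cat("ModelFrame:", nrow(object@X), "participants\n")
    cat("  X:", sum(object@roles == "brain_feature"), "brain features +",
        sum(object@roles == "covariate"), "covariates (z-scored)\n")
    cat("  Y:", ncol(object@Y), "indicators (z-scored):",
        paste(colnames(object@Y), collapse = ", "), "\n")
})
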
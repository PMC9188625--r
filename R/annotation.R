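.alignWeights <- function(weights, terms) {
    if (is(weights, "BaggedSolution")) weights <- weights@mean
    if (is(weights, "RidgeSolution")) weights <- coef(weights)
    if (is.null(dim(weights)))
        weights <- matrix(weights, ncol = 1L,
                          dimnames = list(names(weights), "map"))
    regions <- rownames(terms)
    if (is.null(regions) || is.null(rownames(weights)))
        stop("terms and weights must carry feature_id rownames")
    missing <- setdiff(regions, rownames(weights))
    if (length(missing))
        stop("regions missing from weight map: ",
             paste(missing, collapse = ", "))
    if (length(regions) < 3L) stop("at least 3 regions required")
    weights[regions, , drop = FALSE]
}

.termCor <- function(W, terms, mode) {
    sds <- apply(terms, 2, sd)
    if (any(sds <= 1e-12))
        stop("zero-variance term column: ",
             paste(colnames(terms)[sds <= 1e-12], collapse = ", "))
    grid <- expand.grid(term = colnames(terms),
                        indicator = colnames(W),
                        stringsAsFactors = FALSE)
    grid$r <- mapply(function(t, i) cor(terms[, t], W[, i]),
                     grid$term, grid$indicator)
    grid$mode <- mode
    rownames(grid) <- NULL
    grid
}

#' Meta-analytic term profiling of coefficient maps
#'
#' Correlates each term column of a gray-matter region-by-term association
#' matrix with the regional coefficient values of each SES indicator map,
#' yielding one Pearson r per (term, indicator).
#'
#' @param weights region coefficient map: named vector, region-by-k matrix,
#'   [RidgeSolution-class] or [BaggedSolution-class] (rownames must cover
#'   the term-matrix regions).
#' @param terms region-by-term matrix as from [makeTermMatrix()] (rownames
#'   = feature_id).
#' @return data.frame with columns `term`, `indicator`, `r`, `mode`.
#' @export
profileTerms <- function(weights, terms) {
    W <- .alignWeights(weights, terms)
    .termCor(W, terms, "full")
}

#' @rdname profileTerms
#' @param atlas atlas data.frame for hemisphere lookup.
#' @param hemisphere `"L"` or `"R"`.
#' @export
profileByHemisphere <- function(weights, terms, atlas,
                                hemisphere = c("L", "R")) {
    hemisphere <- match.arg(hemisphere)
    keep <- intersect(rownames(terms),
                      atlas$feature_id[atlas$hemisphere == hemisphere])
    if (length(keep) < 3L)
        stop("fewer than 3 regions in hemisphere ", hemisphere)
    termsH <- terms[keep, , drop = FALSE]
    W <- .alignWeights(weights, termsH)
    .termCor(W, termsH, paste0("by_hemisphere:", hemisphere))
}

#' Unique (partial-regression) term profile of one indicator
#'
#' Residualizes the target indicator's regional map on the other maps
#' (least squares with intercept, across regions) before term correlation,
#' isolating meta-analytic associations uniquely explained by that
#' indicator.
#'
#' @param maps region-by-k matrix of all indicator coefficient maps.
#' @param terms region-by-term matrix.
#' @param indicator column name (or index) of the target indicator.
#' @return data.frame as in [profileTerms()] with `mode = "unique"`.
#' @export
uniqueProfile <- function(maps, terms, indicator) {
    maps <- .alignWeights(maps, terms)
    if (ncol(maps) < 2L)
        stop("unique profiling needs at least 2 indicator maps")
    if (is.numeric(indicator)) indicator <- colnames(maps)[indicator]
    if (!indicator %in% colnames(maps))
        stop("unknown indicator: ", indicator)
    target <- maps[, indicator]
    others <- maps[, setdiff(colnames(maps), indicator), drop = FALSE]
    res <- qr.resid(qr(cbind(1, others)), target)
    if (sd(res) <= 1e-10)
        stop("degenerate residual: '", indicator,
             "' map is (nearly) a linear combination of the other maps")
    resMap <- matrix(res, ncol = 1L,
                     dimnames = list(rownames(maps), indicator))
    out <- .termCor(resMap, terms, "unique")
    out
}
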
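#' Pairwise Pearson correlations of the SES indicators
#'
#' @param ses n-by-6 matrix or data.frame of (oriented) indicators, complete
#'   cases.
#' @return symmetric 6x6 correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(ses) {
    ses <- as.matrix(ses)
    if (anyNA(ses)) stop("complete cases required")
    sds <- apply(ses, 2, sd)
    if (any(sds <= 1e-12))
        stop("constant indicator: ",
             paste(colnames(ses)[sds <= 1e-12], collapse = ", "))
    cor(ses)
}

#' Principal component mixture decomposition of the SES indicators
#'
#' Eigendecomposition of the indicator correlation matrix (equivalent to PCA
#' of the z-scored indicators). Explained-variance ratios are the
#' eigenvalues divided by the indicator count, hence non-increasing and
#' summing to one. Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param ses n-by-k indicator matrix (k = 6 in the standard pipeline).
#' @return list of class `PCAResult` with `loadings` (k-by-k),
#'   `explainedVarianceRatio`, `eigenvalues` and `scores` (n-by-k, from the
#'   z-scored data).
#' @export
pcaDecompose <- function(ses) {
    ses <- as.matrix(ses)
    R <- pairwiseCorrelation(ses)
    ev <- eigen(R, symmetric = TRUE)
    if (ev$values[1L] <= 1e-12) stop("rank collapse: no variance to decompose")
    V <- ev$vectors
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    dimnames(V) <- list(colnames(ses), sprintf("PC%d", seq_len(ncol(V))))
    Z <- scale(ses)
    scores <- Z %*% V
    out <- list(loadings = V,
                explainedVarianceRatio = ev$values / ncol(ses),
                eigenvalues = ev$values,
                scores = scores)
    class(out) <- "PCAResult"
    out
}

#' Univariate association of each indicator with a demographic covariate
#'
#' Slope of the standardized indicator on the standardized covariate, which
#' equals their Pearson correlation.
#'
#' @param ses indicator matrix/data.frame.
#' @param covariate aligned numeric vector (e.g. age or sex).
#' @return named vector of standardized slopes, one per indicator.
#' @export
univariateAssoc <- function(ses, covariate) {
    ses <- as.matrix(ses)
    if (length(covariate) != nrow(ses))
        stop("covariate length mismatch")
    if (sd(covariate) <= 1e-12) stop("constant covariate")
    vapply(seq_len(ncol(ses)), function(j) cor(ses[, j], covariate),
           numeric(1)) |> stats::setNames(colnames(ses))
}

#' Regression of brain features onto SES principal components
#'
#' Refits the multi-output model with the standardized component scores as
#' outcomes (classical linear regression when `alpha = 0`), to check that
#' laterality patterns persist at the component level.
#'
#' @param x standardized design matrix or [ModelFrame-class].
#' @param scores component score matrix from [pcaDecompose()].
#' @param alpha penalty strength (default 0: ordinary least squares).
#' @param config optional full [ridgeConfig()] overriding `alpha`.
#' @return a [RidgeSolution-class] over components.
#' @export
pcRegression <- function(x, scores, alpha = 0, config = NULL) {
    if (is.null(config)) config <- ridgeConfig(alpha = alpha)
    X <- if (is(x, "ModelFrame")) x@X else as.matrix(x)
    Z <- standardize(as.matrix(scores))$values
    fitRidge(X, Z, config)
}
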
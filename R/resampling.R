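#' Bootstrap aggregation of the multi-output fit
#'
#' Refits the full standardized model on `B` n-out-of-n with-replacement
#' participant resamples and summarizes the coefficient ensemble (elementwise
#' mean, standard deviation and 5%/95% percentile bounds). Residualization
#' and standardization are those of the supplied model frame, fitted once on
#' the full analysis sample. A resample that turns a non-constant outcome
#' column constant is redrawn and the event counted.
#'
#' @param frame a [ModelFrame-class].
#' @param config a [ridgeConfig()].
#' @param B resample count (default 100, >= 2).
#' @param seed integer RNG seed; results are bit-identical under a fixed
#'   seed.
#' @return a [BaggedSolution-class].
#' @export
bootstrapBag <- function(frame, config = ridgeConfig(), B = 100L,
                         seed = 1L) {
    B <- as.integer(B)
    if (B < 2L) stop("B must be >= 2 for interval formation")
    xy <- .getXY(frame)
    X <- xy$X
    Y <- xy$Y
    n <- nrow(X)
    p <- ncol(X)
    k <- ncol(Y)
    baseConstant <- apply(Y, 2, sd) <= 1e-12
    set.seed(as.integer(seed))
    draws <- array(NA_real_, dim = c(B, p, k),
                   dimnames = list(NULL, colnames(X), colnames(Y)))
    redraws <- 0L
    b <- 1L
    while (b <= B) {
        idx <- sample.int(n, n, replace = TRUE)
        Yb <- Y[idx, , drop = FALSE]
        degenerate <- apply(Yb, 2, sd) <= 1e-12 & !baseConstant
        if (any(degenerate)) {
            redraws <- redraws + 1L
            if (redraws > 1000L)
                stop("too many degenerate bootstrap resamples")
            next
        }
        draws[b, , ] <- coef(.fitRidgeCore(X[idx, , drop = FALSE], Yb,
                                           config))
        b <- b + 1L
    }
    if (redraws > 0L)
        message("bootstrapBag: redrew ", redraws, " degenerate resample(s)")
    mn <- apply(draws, c(2, 3), mean)
    sdm <- apply(draws, c(2, 3), sd)
    lo <- apply(draws, c(2, 3), quantile, probs = 0.05, names = FALSE)
    hi <- apply(draws, c(2, 3), quantile, probs = 0.95, names = FALSE)
    dimnames(lo) <- dimnames(hi) <- dimnames(mn)
    new("BaggedSolution", mean = mn, sd = sdm, lo5 = lo, hi95 = hi,
        draws = draws, B = B, seed = as.integer(seed), redraws = redraws)
}

#' Accessors for BaggedSolution summaries
#'
#' @param x a [BaggedSolution-class].
#' @return p-by-k matrix (`baggedMean`, `baggedSD`, `baggedLower`,
#'   `baggedUpper`) or the raw B-by-p-by-k draw array (`baggedDraws`).
#' @export
baggedMean <- function(x) x@mean

#' @rdname baggedMean
#' @export
baggedSD <- function(x) x@sd

#' @rdname baggedMean
#' @export
baggedLower <- function(x) x@lo5

#' @rdname baggedMean
#' @export
baggedUpper <- function(x) x@hi95

#' @rdname baggedMean
#' @export
baggedDraws <- function(x) x@draws

setMethod("show", "BaggedSolution", function(object) {
    cat(sprintf(
        "BaggedSolution: %d x %d coefficients over B = %d resamples (seed %d)\n",
        nrow(object@mean), ncol(object@mean), object@B, object@seed))
    if (object@redraws > 0L)
        cat("  degenerate resamples redrawn:", object@redraws, "\n")
})

#' Permutation max-statistic null distribution
#'
#' For each of `R` permutations the outcome rows are shuffled as a block (the
#' six indicators stay together; the design matrix is held constant), the
#' multi-output model is refit, and the maximum absolute coefficient over all
#' p-by-k cells is recorded. The null fit uses the closed-form ridge solution
#' (numerically within solver tolerance of coordinate descent). With
#' `mode = "bagged_fit"` each permutation is additionally bagged over
#' `B` bootstrap resamples, mirroring the observed statistic exactly at a
#' much higher cost.
#'
#' @param frame a [ModelFrame-class].
#' @param config a [ridgeConfig()].
#' @param R permutation count (default 1000).
#' @param seed integer RNG seed.
#' @param mode `"plain_fit"` (default) or `"bagged_fit"`.
#' @param B bootstrap count for `"bagged_fit"`.
#' @param keepCellStats keep the full R-by-(p*k) matrix of per-cell null
#'   statistics (diagnostics; memory heavy for large R).
#' @return a [PermutationNull-class].
#' @export
permutationNull <- function(frame, config = ridgeConfig(), R = 1000L,
                            seed = 1L, mode = c("plain_fit", "bagged_fit"),
                            B = 100L, keepCellStats = FALSE) {
    mode <- match.arg(mode)
    R <- as.integer(R)
    if (R < 1L) stop("R must be >= 1")
    xy <- .getXY(frame)
    X <- xy$X
    Y <- xy$Y
    n <- nrow(X)
    set.seed(as.integer(seed))
    maxStats <- numeric(R)
    cellStats <- if (keepCellStats)
        matrix(NA_real_, R, ncol(X) * ncol(Y)) else
        matrix(numeric(0), 0, 0)
    if (mode == "plain_fit") {
        G <- crossprod(X) / n
        A <- solve(G + diag(config$alpha, ncol(X)), t(X) / n)
        for (r in seq_len(R)) {
            W <- A %*% Y[sample.int(n), , drop = FALSE]
            if (keepCellStats) cellStats[r, ] <- abs(as.vector(W))
            maxStats[r] <- max(abs(W))
        }
    } else {
        for (r in seq_len(R)) {
            permFrame <- list(X = X, Y = Y[sample.int(n), , drop = FALSE])
            bag <- bootstrapBag(permFrame, config, B = B,
                                seed = sample.int(.Machine$integer.max, 1L))
            if (keepCellStats) cellStats[r, ] <- abs(as.vector(bag@mean))
            maxStats[r] <- max(abs(bag@mean))
        }
    }
    new("PermutationNull", maxStats = maxStats, R = R,
        seed = as.integer(seed), mode = mode, cellStats = cellStats)
}

#' @rdname permutationNull
#' @param x a [PermutationNull-class].
#' @export
maxStats <- function(x) x@maxStats

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull: R = %d (%s, seed %d), max-stat range [%.4g, %.4g]\n",
                object@R, object@mode, object@seed,
                min(object@maxStats), max(object@maxStats)))
})

#' Family-wise-error corrected p-values
#'
#' Two-sided permutation p-values under the max-statistic family-wise-error
#' construction, with the add-one counting convention
#' `p = (1 + #\{r : maxStat_r >= |observed|\}) / (1 + R)`; ties count against
#' significance and p-values are never zero.
#'
#' @param observed a [BaggedSolution-class] (its bagged mean is the observed
#'   statistic), a [RidgeSolution-class], or a p-by-k matrix.
#' @param null a [PermutationNull-class] computed on the same model frame.
#' @param threshold significance threshold on the corrected p-values
#'   (default 0.001).
#' @return a [SignificanceReport-class].
#' @export
fwePvalues <- function(observed, null, threshold = 0.001) {
    obs <- if (is(observed, "BaggedSolution")) observed@mean
           else if (is(observed, "RidgeSolution")) coef(observed)
           else as.matrix(observed)
    ms <- null@maxStats
    R <- null@R
    av <- abs(as.vector(obs))
    counts <- vapply(av, function(v) sum(ms >= v), numeric(1))
    p <- matrix((1 + counts) / (1 + R), nrow(obs), ncol(obs),
                dimnames = dimnames(obs))
    new("SignificanceReport", pFWE = p, significant = p < threshold,
        threshold = threshold, R = R)
}

#' Accessors for SignificanceReport
#'
#' @param x a [SignificanceReport-class].
#' @return `pFWE()` the corrected p-value matrix, `significantCells()` the
#'   logical flag matrix.
#' @export
pFWE <- function(x) x@pFWE

#' @rdname pFWE
#' @export
significantCells <- function(x) x@significant

setMethod("show", "SignificanceReport", function(object) {
    cat(sprintf(
        "SignificanceReport: %d of %d cells significant at p < %g (R = %d)\n",
        sum(object@significant), length(object@significant),
        object@threshold, object@R))
})
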
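#' Ridge estimation settings
#'
#' The estimator minimizes `(1/(2n))||Y - XW||_F^2 + (alpha/2)||W||_F^2`
#' over the p-by-k slope matrix W, on centered (z-scored) data with no
#' intercept. Note the 1/n scaling of the loss: in the common un-normalized
#' convention the equivalent penalty is `n * alpha`.
#'
#' @param alpha l2 regularization strength, >= 0 (default 0.01).
#' @param solver `"closed_form"` (normal equations) or
#'   `"coordinate_descent"` (cyclic full passes in fixed column order).
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   absolute coefficient change per sweep.
#' @param maxIter coordinate-descent sweep cap.
#' @return list of class `RidgeConfig`.
#' @export
ridgeConfig <- function(alpha = 0.01,
                        solver = c("closed_form", "coordinate_descent"),
                        tol = 1e-8, maxIter = 10000L) {
    if (alpha < 0) stop("alpha must be >= 0")
    if (tol <= 0) stop("tol must be > 0")
    cfg <- list(alpha = as.numeric(alpha), solver = match.arg(solver),
                tol = as.numeric(tol), maxIter = as.integer(maxIter))
    class(cfg) <- "RidgeConfig"
    cfg
}

# Gram-matrix solvers. G = X'X/n, C = X'Y/n; stationarity of the objective
# gives (G + alpha I) W = C.
.ridgeClosedForm <- function(G, C, alpha) {
    solve(G + diag(alpha, nrow(G)), C)
}

.ridgeCoordinateDescent <- function(G, C, alpha, tol, maxIter) {
    p <- nrow(G)
    k <- ncol(C)
    W <- matrix(0, p, k)
    denom <- diag(G) + alpha
    if (any(denom <= 0))
        stop("zero design column with alpha = 0: coordinate update undefined")
    for (it in seq_len(maxIter)) {
        delta <- 0
        for (j in seq_len(p)) {
            resid <- C[j, ] - drop(G[j, , drop = FALSE] %*% W) + G[j, j] * W[j, ]
            wNew <- resid / denom[j]
            delta <- max(delta, max(abs(wNew - W[j, ])))
            W[j, ] <- wNew
        }
        if (delta < tol)
            return(list(W = W, iterations = it))
    }
    stop(sprintf(
        "coordinate descent did not converge in %d sweeps (last max change %.3e)",
        maxIter, delta))
}

.fitRidgeCore <- function(X, Y, config) {
    n <- nrow(X)
    if (n < 2L) stop("at least 2 participants required")
    G <- crossprod(X) / n
    C <- crossprod(X, Y) / n
    if (config$solver == "closed_form") {
        W <- .ridgeClosedForm(G, C, config$alpha)
        it <- 0L
    } else {
        fit <- .ridgeCoordinateDescent(G, C, config$alpha, config$tol,
                                       config$maxIter)
        W <- fit$W
        it <- fit$iterations
    }
    dimnames(W) <- list(colnames(X), colnames(Y))
    new("RidgeSolution", coefficients = W, alpha = config$alpha,
        solver = config$solver, iterations = as.integer(it))
}

#' Fit the multi-output ridge model
#'
#' Returns the minimizer of the Frobenius-penalized least-squares objective
#' (see [ridgeConfig()]); with the pure l2 penalty the problem is separable,
#' so each column of the solution equals the single-output ridge fit of that
#' indicator alone — an exact algebraic identity used by the test suite.
#'
#' @param x standardized design matrix or a [ModelFrame-class].
#' @param y standardized outcome matrix (ignored when `x` is a ModelFrame).
#' @param config a [ridgeConfig()].
#' @return a [RidgeSolution-class].
#' @export
setGeneric("fitRidge", function(x, y, config = ridgeConfig())
    standardGeneric("fitRidge"))

#' @rdname fitRidge
setMethod("fitRidge", signature(x = "matrix", y = "matrix"),
    function(x, y, config = ridgeConfig()) {
        if (nrow(x) != nrow(y)) stop("x and y row counts differ")
        .fitRidgeCore(x, as.matrix(y), config)
    })

#' @rdname fitRidge
setMethod("fitRidge", signature(x = "ModelFrame", y = "missing"),
    function(x, y, config = ridgeConfig()) {
        .fitRidgeCore(x@X, x@Y, config)
    })

#' @rdname fitRidge
#' @param object a [RidgeSolution-class].
#' @param ... unused.
#' @export
setMethod("coef", "RidgeSolution", function(object, ...) object@coefficients)

setMethod("show", "RidgeSolution", function(object) {
    cat(sprintf("RidgeSolution: %d x %d coefficients (alpha = %g, %s",
                nrow(object@coefficients), ncol(object@coefficients),
                object@alpha, object@solver))
    if (object@solver == "coordinate_descent")
        cat(sprintf(", %d sweeps", object@iterations))
    cat(")\n")
})

#' Predict outcomes from a fitted solution
#'
#' Computes `Yhat = X W`; the model carries no intercept because design and
#' outcomes are centered.
#'
#' @param object a [RidgeSolution-class].
#' @param newdata design matrix with columns matching the fitted features.
#' @param ... unused.
#' @return predicted outcome matrix.
#' @export
setMethod("predict", "RidgeSolution", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != nrow(object@coefficients))
        stop("shape mismatch: newdata has ", ncol(newdata),
             " columns, coefficients expect ", nrow(object@coefficients))
    newdata %*% object@coefficients
})

#' Out-of-sample prediction metrics
#'
#' Per indicator and pooled (unweighted mean over indicators): Pearson's r,
#' explained variance score `1 - Var(y - yhat)/Var(y)`, mean absolute error,
#' coefficient of determination `1 - SS_res/SS_tot`, and mean squared error.
#' The two variance-based scores differ when predictions are mean-biased.
#'
#' @param y observed outcome matrix.
#' @param yhat predicted outcome matrix of the same shape.
#' @return data.frame with one row per indicator plus a `"pooled"` row.
#' @export
scoreMetrics <- function(y, yhat) {
    y <- as.matrix(y)
    yhat <- as.matrix(yhat)
    if (!identical(dim(y), dim(yhat)))
        stop("y and yhat shapes differ")
    vars <- apply(y, 2, var)
    if (any(vars <= 1e-12))
        stop("zero-variance outcome column: ",
             paste(colnames(y)[vars <= 1e-12], collapse = ", "))
    perCol <- function(j) {
        e <- y[, j] - yhat[, j]
        r <- if (sd(yhat[, j]) <= 1e-12) NA_real_ else cor(y[, j], yhat[, j])
        c(pearson_r = r,
          explained_variance_score = 1 - var(e) / var(y[, j]),
          mean_absolute_error = mean(abs(e)),
          coefficient_of_determination =
              1 - sum(e^2) / sum((y[, j] - mean(y[, j]))^2),
          mean_squared_error = mean(e^2))
    }
    m <- t(vapply(seq_len(ncol(y)), perCol, numeric(5)))
    rownames(m) <- colnames(y)
    out <- rbind(m, pooled = colMeans(m, na.rm = TRUE))
    data.frame(indicator = rownames(out), out, row.names = NULL,
               check.names = FALSE)
}

#' Map standardized coefficients back to the raw scale
#'
#' Multiplies each standardized slope by sd(outcome)/sd(design column) using
#' the transformation parameters recorded in the model frame, so estimates
#' can be compared with effects stated on the raw (pre-z-scoring) scale.
#'
#' @param coefficients p-by-k matrix, [RidgeSolution-class] or
#'   [BaggedSolution-class] mean.
#' @param frame the [ModelFrame-class] the model was fitted on.
#' @return p-by-k matrix on the raw scale.
#' @export
destandardizeCoefficients <- function(coefficients, frame) {
    W <- if (is(coefficients, "RidgeSolution")) coef(coefficients)
         else if (is(coefficients, "BaggedSolution")) coefficients@mean
         else as.matrix(coefficients)
    xs <- frame@xStandardization$scale[rownames(W)]
    ys <- frame@yStandardization$scale[colnames(W)]
    sweep(sweep(W, 2, ys, "*"), 1, xs, "/")
}
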
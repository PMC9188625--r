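test_that("the penalized objective has the expected closed form", {
    # p = k = 1, X = (1,-1)', Y = (1,-1)': minimizer is 1/(1+alpha)
    X <- matrix(c(1, -1), 2, 1)
    Y <- matrix(c(1, -1), 2, 1)
    w <- coef(fitRidge(X, Y, ridgeConfig(alpha = 0.01)))
    expect_equal(as.numeric(w), 1 / 1.01, tolerance = 1e-12)

    # alpha = 0 reduces to ordinary least squares
    set.seed(10)
    X <- matrix(rnorm(100 * 8), 100)
    Y <- matrix(rnorm(100 * 3), 100)
    Wols <- qr.coef(qr(X), Y)
    W0 <- coef(fitRidge(X, Y, ridgeConfig(alpha = 0)))
    expect_lt(max(abs(W0 - Wols)), 1e-8)
})

test_that("coordinate descent agrees with the closed form and is separable", {
    set.seed(11)
    for (rep in 1:5) {
        X <- matrix(rnorm(500 * 30), 500)
        Y <- matrix(rnorm(500 * 6), 500)
        cf <- coef(fitRidge(X, Y, ridgeConfig(solver = "closed_form")))
        cd <- coef(fitRidge(X, Y,
                            ridgeConfig(solver = "coordinate_descent")))
        expect_lt(max(abs(cf - cd)), 1e-8)
        expect_lt(max(abs(cf - oracleRidge(X, Y, 0.01))), 1e-10)
        # separability: multi-output column j = single-output fit of column j
        for (j in c(1L, 4L)) {
            single <- coef(fitRidge(X, Y[, j, drop = FALSE], ridgeConfig()))
            expect_lt(max(abs(cf[, j] - single)), 1e-10)
        }
    }
})

test_that("coefficient norm shrinks monotonically in alpha", {
    set.seed(12)
    X <- matrix(rnorm(200 * 10), 200)
    Y <- matrix(rnorm(200 * 4), 200)
    norms <- vapply(c(0, 0.01, 0.1, 1, 10), function(a)
        sqrt(sum(coef(fitRidge(X, Y, ridgeConfig(alpha = a)))^2)),
        numeric(1))
    expect_true(all(diff(norms) <= 1e-12))
})

test_that("the fit is equivariant under joint row permutation", {
    set.seed(13)
    X <- matrix(rnorm(120 * 7), 120)
    Y <- matrix(rnorm(120 * 6), 120)
    perm <- sample(120)
    W1 <- coef(fitRidge(X, Y, ridgeConfig()))
    W2 <- coef(fitRidge(X[perm, ], Y[perm, ], ridgeConfig()))
    expect_lt(max(abs(W1 - W2)), 1e-10)
})

test_that("coordinate descent reports non-convergence", {
    set.seed(14)
    X <- matrix(rnorm(50 * 5), 50)
    Y <- matrix(rnorm(50 * 2), 50)
    expect_error(
        fitRidge(X, Y, ridgeConfig(solver = "coordinate_descent",
                                   tol = 1e-14, maxIter = 2L)),
        "did not converge.*max change")
})

test_that("prediction is the plain linear map", {
    set.seed(15)
    X <- matrix(rnorm(40 * 5), 40)
    Y <- matrix(rnorm(40 * 2), 40)
    fit <- fitRidge(X, Y, ridgeConfig())
    expect_equal(predict(fit, X), X %*% coef(fit))
    zero <- fit
    zero@coefficients[] <- 0
    expect_true(all(predict(zero, X) == 0))
    expect_error(predict(fit, X[, 1:3]), "shape mismatch")
})

test_that("noiseless planted cohorts are recovered with correlation 1", {
    cfg <- tinyConfig(nParticipants = 500L, outcomeNoiseSD = 0,
                      ordinalBins = continuousBins, confoundEffectSD = 0,
                      seed = 23L)
    coh <- simulateCohort(cfg)
    X <- standardize(brainFeatures(coh))$values
    Y <- standardize(as.matrix(orientIndicators(sesTable(coh))))$values
    fit <- fitRidge(X, Y, ridgeConfig(alpha = 0))
    pred <- predict(fit, X)
    for (j in seq_len(6L))
        expect_equal(cor(pred[, j], Y[, j]), 1, tolerance = 1e-8)
})

test_that("the metric suite matches hand-computed values", {
    set.seed(16)
    Y <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("u", "v")))

    perfect <- scoreMetrics(Y, Y)
    expect_equal(perfect$pearson_r, rep(1, 3))
    expect_equal(perfect$explained_variance_score, rep(1, 3))
    expect_equal(perfect$mean_absolute_error, rep(0, 3))
    expect_equal(perfect$coefficient_of_determination, rep(1, 3))

    # constant mean predictor: EVS = 0, R^2 = 0, MSE = population variance
    Ybar <- matrix(rep(colMeans(Y), each = 30), 30)
    mp <- scoreMetrics(Y, Ybar)
    expect_equal(mp$explained_variance_score[1:2], c(0, 0))
    expect_equal(mp$coefficient_of_determination[1:2], c(0, 0))
    popVar <- apply(Y, 2, function(y) mean((y - mean(y))^2))
    expect_equal(mp$mean_squared_error[1:2], unname(popVar))

    # biased predictions expose the EVS / R^2 gap
    y10 <- matrix(scale(rnorm(10)), ncol = 1, dimnames = list(NULL, "y"))
    biased <- scoreMetrics(y10, y10 + 0.5)
    expect_equal(biased$explained_variance_score[1], 1)
    r2Hand <- 1 - 0.25 * 10 / sum((y10 - mean(y10))^2)
    expect_equal(biased$coefficient_of_determination[1], r2Hand)
    expect_lt(biased$coefficient_of_determination[1], 1)
    expect_lte(biased$coefficient_of_determination[1],
               biased$explained_variance_score[1] + 1e-12)

    Yc <- Y
    Yc[, 2] <- 3
    expect_error(scoreMetrics(Yc, Y), "zero-variance")
})

test_that("cross-validated benchmark is seeded, honest and extensible", {
    noiseless <- simulateCohort(tinyConfig(nParticipants = 400L,
                                           outcomeNoiseSD = 0,
                                           ordinalBins = continuousBins,
                                           confoundEffectSD = 0,
                                           seed = 41L))
    rep1 <- crossvalBenchmark(noiseless, models = "ridge", nFolds = 5,
                              seed = 2L)
    rep2 <- crossvalBenchmark(noiseless, models = "ridge", nFolds = 5,
                              seed = 2L)
    expect_identical(rep1, rep2)
    pooled <- rep1$ridge[rep1$ridge$indicator == "pooled", ]
    expect_gte(pooled$pearson_r, 0.99)

    expect_error(crossvalBenchmark(noiseless, models = "boosted_trees"),
                 "unknown model_spec")

    # pure-noise outcomes: out-of-sample EVS hovers at or below zero
    evs <- vapply(1:10, function(s) {
        nullCoh <- simulateCohort(tinyConfig(nParticipants = 250L,
                                             effectScale = 0,
                                             ordinalBins = continuousBins,
                                             seed = 100L + s))
        tab <- crossvalBenchmark(nullCoh, models = "ridge", nFolds = 5,
                                 seed = s)$ridge
        tab$explained_variance_score[tab$indicator == "pooled"]
    }, numeric(1))
    expect_lte(mean(evs), 0.01)
})

test_that("the knn learner plugs into the benchmark registry", {
    coh <- simulateCohort(tinyConfig(nParticipants = 200L, seed = 55L))
    out <- crossvalBenchmark(coh, models = c("ols", "knn"), nFolds = 3,
                             seed = 9L, knnK = 15L)
    expect_named(out, c("ols", "knn"))
    expect_true(all(is.finite(out$knn$mean_squared_error)))
})

test_that("standardized coefficients destandardize back to the raw scale", {
    cfg <- tinyConfig(nParticipants = 2000L, outcomeNoiseSD = 0,
                      ordinalBins = continuousBins, confoundEffectSD = 0,
                      seed = 77L)
    coh <- simulateCohort(cfg)
    frame <- preprocessCohort(coh)
    fit <- fitRidge(frame, config = ridgeConfig(alpha = 0))
    raw <- destandardizeCoefficients(fit, frame)
    W <- cohortTruth(coh)$trueCoefficients
    # residualizing X on an irrelevant nuisance perturbs the noiseless system
    # at O(1/n), so recovery on the raw scale is near-exact, not exact
    expect_lt(max(abs(raw[rownames(W), ] - W)), 5e-3)
    expect_gt(cor(as.vector(raw[rownames(W), ]), as.vector(W)), 0.9999)
})
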
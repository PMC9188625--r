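test_that("simulation is bit-identical under a fixed seed and config", {
    cfg <- tinyConfig(seed = 99L)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(brainFeatures(a), brainFeatures(b))
    expect_identical(sesTable(a), sesTable(b))
    expect_identical(confoundTable(a), confoundTable(b))
    expect_identical(cohortTruth(a), cohortTruth(b))
    c <- simulateCohort(tinyConfig(seed = 100L))
    expect_false(identical(brainFeatures(a), brainFeatures(c)))
})

test_that("noiseless cohort is an exact linear system in the planted truth", {
    cfg <- tinyConfig(nParticipants = 400L, outcomeNoiseSD = 0,
                      ordinalBins = continuousBins, confoundEffectSD = 0,
                      seed = 5L)
    coh <- simulateCohort(cfg)
    X <- brainFeatures(coh)
    Y <- as.matrix(orientIndicators(sesTable(coh)))
    W <- cohortTruth(coh)$trueCoefficients
    What <- qr.coef(qr(cbind(1, X)), Y)[-1L, , drop = FALSE]
    expect_lt(max(abs(What - W)), 1e-8)
})

test_that("indicator correlations follow the single-factor closed form", {
    # with no brain effects the indicators are lambda_i*g + sigma*eps_i, so
    # cor(i, j) = lambda_i*lambda_j / sqrt((lambda_i^2+sigma^2)*(lambda_j^2+sigma^2))
    lam <- c(0.6, 0.6, 0.5, 0.5, 0.4, 0.4)
    sigma <- 1
    cfg <- tinyConfig(nParticipants = 20000L, effectScale = 0,
                      sesLoadings = lam, sesNoiseSD = sigma,
                      ordinalBins = continuousBins, seed = 21L)
    coh <- simulateCohort(cfg)
    emp <- pairwiseCorrelation(orientIndicators(sesTable(coh)))
    expected <- outer(lam, lam) / sqrt(outer(lam^2 + sigma^2,
                                             lam^2 + sigma^2))
    off <- upper.tri(emp)
    expect_true(all(emp[off] < 0.5))
    expect_lt(max(abs(emp[off] - expected[off])), 0.05)
})

test_that("mirrored-pair bookkeeping matches the configured fraction", {
    for (af in c(0, 0.3, 0.5, 1)) {
        coh <- simulateCohort(tinyConfig(asymmetryFraction = af, seed = 7L,
                                         nParticipants = 50L))
        truth <- cohortTruth(coh)
        nPairs <- length(truth$effectPairIds)
        expect_identical(length(truth$asymmetricPairIds),
                         as.integer(round(af * nPairs)))
        atlas <- atlasTable(coh)
        W <- truth$trueCoefficients
        for (pid in truth$asymmetricPairIds) {
            li <- atlas$feature_id[atlas$homologue_id == pid &
                                   atlas$hemisphere == "L"]
            ri <- atlas$feature_id[atlas$homologue_id == pid &
                                   atlas$hemisphere == "R"]
            expect_equal(W[li, ], -W[ri, ])
            expect_true(all(W[li, ] > 0))  # left-positive motif
        }
    }
})

test_that("ordinal binning preserves rank information", {
    cfgCont <- tinyConfig(nParticipants = 10000L,
                          ordinalBins = continuousBins, seed = 31L)
    cfgBin <- tinyConfig(nParticipants = 10000L,
                         ordinalBins = rep(5L, 6L), seed = 31L)
    cont <- sesTable(simulateCohort(cfgCont))
    binned <- sesTable(simulateCohort(cfgBin))
    for (j in seq_len(6L)) {
        rho <- cor(cont[[j]], binned[[j]], method = "spearman")
        expect_gte(rho, 0.9)
    }
})

test_that("null cohorts produce approximately normal features and indicators", {
    skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
    exKurtosis <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3
    seeds <- c(11L, 12L, 13L)
    stats <- sapply(seeds, function(s) {
        coh <- simulateCohort(tinyConfig(nParticipants = 10000L,
                                         effectScale = 0,
                                         ordinalBins = continuousBins,
                                         seed = s))
        m <- cbind(brainFeatures(coh), as.matrix(sesTable(coh)))
        c(skew = mean(abs(apply(m, 2, skewness))),
          kurt = mean(abs(apply(m, 2, exKurtosis))))
    })
    expect_lt(mean(stats["skew", ]), 0.1)
    expect_lt(mean(stats["kurt", ]), 0.2)
})

test_that("generator rejects invalid configurations", {
    expect_error(cohortConfig(nParticipants = 0), "positive")
    expect_error(cohortConfig(asymmetryFraction = 1.5), "\\[0, 1\\]")
    expect_error(cohortConfig(nCorticalPairs = -1), ">= 0")
    expect_error(cohortConfig(nCorticalPairs = 0, nSubcorticalPairs = 0,
                              nMidlineRegions = 0, nTractPairs = 0,
                              nMidlineTracts = 0), "total feature count")
})

test_that("term-matrix fixtures are seeded, bounded and can plant collinearity", {
    coh <- simulateCohort(tinyConfig(seed = 3L))
    atlas <- atlasTable(coh)
    gray <- atlas$feature_id[atlas$tissue %in% c("cortical", "subcortical")]
    map <- stats::setNames(rnorm(length(gray)), gray)

    t1 <- makeTermMatrix(atlas, nTerms = 4L, seed = 8L, collinearWith = map)
    t2 <- makeTermMatrix(atlas, nTerms = 4L, seed = 8L, collinearWith = map)
    expect_identical(t1, t2)
    expect_true(all(t1 >= 0 & t1 <= 1))
    expect_identical(colnames(t1)[1L], "planted")
    expect_equal(cor(t1[, "planted"], map[rownames(t1)]), 1)

    tractsOnly <- atlas[atlas$tissue == "tract", ]
    expect_error(makeTermMatrix(tractsOnly, 3L), "zero gray-matter")
})

test_that("random term columns correlate with a fixed map at null levels", {
    coh <- simulateCohort(tinyConfig(seed = 4L))
    atlas <- atlasTable(coh)
    terms <- makeTermMatrix(atlas, nTerms = 200L, seed = 12L)
    set.seed(1)
    map <- rnorm(nrow(terms))
    rs <- apply(terms, 2, cor, y = map)
    within <- mean(abs(rs) <= 3 / sqrt(nrow(terms)))
    expect_gte(within, 0.95)
})
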
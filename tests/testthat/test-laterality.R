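test_that("homologue pairing follows the atlas and validates it", {
    map <- pairHomologues(miniAtlas())
    expect_identical(nrow(map$pairs), 4L)
    expect_identical(map$midline, "mid")
    expect_true(all(map$pairs$left == c("a_L", "b_L", "c_L", "d_L")))

    dangling <- miniAtlas()[-2, ]  # drop a_R
    expect_error(pairHomologues(dangling), "'a' has 1")

    dup <- miniAtlas()
    dup$hemisphere[2] <- "L"
    expect_error(pairHomologues(dup), "one L and one R")

    coh <- simulateCohort(tinyConfig(seed = 71L))
    genMap <- pairHomologues(atlasTable(coh))
    expect_identical(nrow(genMap$pairs), 10L)   # 6 + 2 + 2 configured pairs
    expect_identical(length(genMap$midline), 2L)
})

test_that("sign counting attributes significant cells to hemisphere and sign", {
    atlas <- miniAtlas()
    map <- pairHomologues(atlas)
    feats <- atlas$feature_id
    est <- matrix(1, length(feats), 6,
                  dimnames = list(feats, defaultOrientationMap()$indicator))
    est[c("a_R", "b_R", "c_R", "d_R"), ] <- -1
    sig <- matrix(TRUE, length(feats), 6, dimnames = dimnames(est))
    p <- matrix(0.0005, length(feats), 6, dimnames = dimnames(est))
    rep <- new("SignificanceReport", pFWE = p, significant = sig,
               threshold = 0.001, R = 1000L)

    tab <- signCountTable(rep, est, map, "all_regions")
    expect_identical(as.vector(tab), c(24L, 0L, 0L, 24L))
    # midline features never counted
    expect_identical(attr(tab, "total"), 48L)

    # no significant cells -> all-zero table
    rep0 <- new("SignificanceReport", pFWE = p * 0 + 1, significant = sig & FALSE,
                threshold = 0.001, R = 1000L)
    tab0 <- signCountTable(rep0, est, map, "all_regions")
    expect_true(all(tab0 == 0L))
    expect_error(chiSquareTest(tab0), "zero margin")

    # deduplicated counting: one count per feature
    tabD <- signCountTable(rep, est, map, "all_regions", dedupe = TRUE)
    expect_identical(sum(tabD), 8L)
})

test_that("a hand-built count pattern yields the hand-computed table", {
    # 20 L+, 5 L-, 8 R+, 17 R- over a 25-pair atlas with one indicator
    atlas <- do.call(rbind, lapply(1:25, function(i)
        data.frame(feature_id = sprintf("r%02d_%s", i, c("L", "R")),
                   name = "x", hemisphere = c("L", "R"), tissue = "cortical",
                   homologue_id = sprintf("r%02d", i))))
    map <- pairHomologues(atlas)
    est <- matrix(0, 50, 1, dimnames = list(atlas$feature_id, "income"))
    lefts <- map$pairs$left
    rights <- map$pairs$right
    est[lefts[1:20], 1] <- 1
    est[lefts[21:25], 1] <- -1
    est[rights[1:8], 1] <- 1
    est[rights[9:25], 1] <- -1
    sig <- matrix(TRUE, 50, 1, dimnames = dimnames(est))
    rep <- new("SignificanceReport", pFWE = sig * 0 + 1e-4, significant = sig,
               threshold = 0.001, R = 1000L)
    tab <- signCountTable(rep, est, map, "all_regions")
    expect_identical(as.vector(t(tab)), c(20L, 5L, 8L, 17L))

    out <- chiSquareTest(tab)
    expect_equal(round(out$statistic, 3), 11.688)
    expect_identical(out$df, 1L)
})

test_that("the Pearson statistic matches exhaustive closed-form evaluation", {
    # all 2x2 tables with positive margins and total <= 12
    for (a in 0:12) for (b in 0:(12 - a)) for (d0 in 0:(12 - a - b))
        for (e in 0:(12 - a - b - d0)) {
            tab <- matrix(c(a, d0, b, e), 2, 2)
            if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
            n <- sum(tab)
            stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
                prod(rowSums(tab)) / prod(colSums(tab))
            got <- chiSquareTest(tab)
            expect_equal(got$statistic, stat, tolerance = 1e-12)
            expect_equal(got$p, chisqSF(stat, 1), tolerance = 1e-12)
        }
})

test_that("independence and hemisphere relabeling behave as expected", {
    flat <- matrix(10, 2, 2)
    out <- chiSquareTest(flat)
    expect_equal(out$statistic, 0)
    expect_equal(out$p, 1)

    tab <- matrix(c(20, 8, 5, 17), 2, 2)
    swapped <- tab[2:1, ]
    expect_equal(chiSquareTest(tab)$statistic,
                 chiSquareTest(swapped)$statistic)

    yates <- chiSquareTest(tab, correction = "yates")
    expect_lt(yates$statistic, chiSquareTest(tab)$statistic)
})

test_that("the chi-squared survival function matches reference tail values", {
    expect_equal(round(chisqSF(4.991, 1), 3), 0.025)
    expect_equal(round(chisqSF(0.202, 1), 3), 0.653)
    expect_equal(chisqSF(0, 1), 1)
    # df = 1 equals the two-sided normal tail of sqrt(statistic)
    expect_equal(chisqSF(4.991, 1), 2 * pnorm(sqrt(4.991), lower.tail = FALSE))
    expect_error(chisqSF(-1, 1), ">= 0")
})

test_that("homologue correlations detect mirror symmetry exactly", {
    atlas <- miniAtlas()
    map <- pairHomologues(atlas)
    set.seed(81)
    vals <- matrix(rnorm(9 * 6), 9,
                   dimnames = list(atlas$feature_id,
                                   defaultOrientationMap()$indicator))
    mirrored <- vals
    mirrored[map$pairs$right, ] <- -mirrored[map$pairs$left, ]
    expect_equal(homologueCorrelation(mirrored, map)$r, -1)
    same <- vals
    same[map$pairs$right, ] <- same[map$pairs$left, ]
    expect_equal(homologueCorrelation(same, map)$r, 1)

    # symmetric in pair order
    swapped <- map
    names(swapped$pairs)[2:3] <- c("right", "left")
    expect_equal(homologueCorrelation(vals, swapped)$r,
                 homologueCorrelation(vals, map)$r)

    perInd <- homologueCorrelation(vals, map, perIndicator = TRUE)
    expect_identical(nrow(perInd), 7L)
    expect_true(all(perInd$r >= -1 & perInd$r <= 1))

    expect_error(homologueCorrelation(vals, map, subset = "tracts"),
                 "fewer than 3")
})

test_that("null cohorts give homologue correlations centered on zero", {
    rs <- vapply(1:50, function(s) {
        coh <- simulateCohort(tinyConfig(nParticipants = 400L,
                                         effectScale = 0, seed = 400L + s))
        frame <- preprocessCohort(coh)
        fit <- fitRidge(frame)
        map <- pairHomologues(atlasTable(coh))
        homologueCorrelation(coef(fit), map)$r
    }, numeric(1))
    nPairs <- 10
    expect_lte(mean(abs(rs)), 2 / sqrt(nPairs))
    expect_lt(abs(mean(rs)), 0.15)
})

test_that("the asymmetry summary assembles tests and correlation grids", {
    coh <- simulateCohort(tinyConfig(nParticipants = 3000L,
                                     asymmetryFraction = 0.5, seed = 83L))
    frame <- preprocessCohort(coh)
    bag <- bootstrapBag(frame, B = 30, seed = 1L)
    null <- permutationNull(frame, R = 99, seed = 2L)
    rep <- fwePvalues(bag, null, threshold = 0.02)
    map <- pairHomologues(atlasTable(coh))
    asym <- asymmetrySummary(bag, rep, map)

    expect_true(all(c("gray_matter", "tracts") %in% names(asym$signTables)))
    pooled <- asym$correlationsPlain[
        asym$correlationsPlain$indicator == "pooled" &
        asym$correlationsPlain$subset == "all_regions", ]
    expect_lt(pooled$r, -0.3)  # half the pairs carry the mirrored motif
    pooledZ <- asym$correlations[asym$correlations$indicator == "pooled" &
                                 asym$correlations$subset == "all_regions", ]
    expect_lt(pooledZ$r, 0)    # uncertainty-adjusted map agrees in direction
    expect_true(all(c("all_regions", "gray_matter", "cortical") %in%
                    asym$correlations$subset))
    expect_identical(names(asym$meanPerIndicatorR),
                     sort(unique(asym$correlations$subset)))
    expect_output(print(asym), "pooled homologue r")
})
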
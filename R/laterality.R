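#' Pair homologous left/right features
#'
#' Builds the homologue pairing from shared `homologue_id`s; midline (M)
#' features are listed separately and excluded from all laterality
#' statistics.
#'
#' @param atlas atlas data.frame as from [atlasTable()].
#' @return list of class `HomologueMap` with `pairs` (data.frame:
#'   `homologue_id`, `left`, `right`, `tissue`) and `midline` (feature ids).
#' @export
pairHomologues <- function(atlas) {
    atlas <- as.data.frame(atlas)
    hid <- atlas$homologue_id
    lateral <- !is.na(hid) & hid != ""
    if (anyDuplicated(atlas$feature_id))
        stop("duplicate feature_id in atlas")
    ids <- unique(hid[lateral])
    pairs <- lapply(ids, function(pid) {
        members <- atlas[lateral & hid == pid, , drop = FALSE]
        if (nrow(members) != 2L)
            stop("homologue_id '", pid, "' has ", nrow(members),
                 " member(s); expected exactly 2")
        if (!setequal(members$hemisphere, c("L", "R")))
            stop("homologue_id '", pid,
                 "' must have one L and one R member")
        data.frame(homologue_id = pid,
                   left = members$feature_id[members$hemisphere == "L"],
                   right = members$feature_id[members$hemisphere == "R"],
                   tissue = members$tissue[1L], stringsAsFactors = FALSE)
    })
    out <- list(pairs = if (length(pairs)) do.call(rbind, pairs) else
                    data.frame(homologue_id = character(0),
                               left = character(0), right = character(0),
                               tissue = character(0)),
                midline = atlas$feature_id[!lateral])
    class(out) <- "HomologueMap"
    out
}

.subsetPairs <- function(map, subset) {
    subset <- match.arg(subset, c("all_regions", "gray_matter", "cortical",
                                  "subcortical", "tracts"))
    keep <- switch(subset,
                   all_regions = rep(TRUE, nrow(map$pairs)),
                   gray_matter = map$pairs$tissue %in%
                       c("cortical", "subcortical"),
                   cortical = map$pairs$tissue == "cortical",
                   subcortical = map$pairs$tissue == "subcortical",
                   tracts = map$pairs$tissue == "tract")
    pairs <- map$pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) stop("empty subset: ", subset)
    pairs
}

#' Hemisphere-by-sign contingency table of significant associations
#'
#' Each significant (feature, indicator) cell on a lateralized feature
#' contributes one count to (hemisphere of the feature, sign of its bagged
#' coefficient); midline features are excluded. With `dedupe = TRUE` each
#' feature counts at most once, with the sign of its largest-magnitude
#' significant cell.
#'
#' @param report a [SignificanceReport-class].
#' @param bagged a [BaggedSolution-class] (or coefficient matrix) giving the
#'   signed estimates.
#' @param map a `HomologueMap` from [pairHomologues()].
#' @param subset one of `"all_regions"`, `"gray_matter"`, `"cortical"`,
#'   `"subcortical"`, `"tracts"`.
#' @param dedupe count each feature at most once.
#' @return 2x2 integer matrix (rows L/R, columns positive/negative) with
#'   attributes `subset` and `total`.
#' @export
signCountTable <- function(report, bagged, map, subset = "all_regions",
                           dedupe = FALSE) {
    est <- if (is(bagged, "BaggedSolution")) bagged@mean else
        as.matrix(bagged)
    pairs <- .subsetPairs(map, subset)
    tab <- matrix(0L, 2L, 2L,
                  dimnames = list(hemisphere = c("L", "R"),
                                  sign = c("positive", "negative")))
    for (hemi in c("L", "R")) {
        feats <- if (hemi == "L") pairs$left else pairs$right
        feats <- intersect(feats, rownames(est))
        for (f in feats) {
            sig <- significantCells(report)[f, ]
            if (!any(sig)) next
            if (dedupe) {
                j <- which(sig)[which.max(abs(est[f, sig]))]
                s <- if (est[f, j] > 0) "positive" else "negative"
                tab[hemi, s] <- tab[hemi, s] + 1L
            } else {
                pos <- sum(sig & est[f, ] > 0)
                neg <- sum(sig & est[f, ] < 0)
                tab[hemi, "positive"] <- tab[hemi, "positive"] + pos
                tab[hemi, "negative"] <- tab[hemi, "negative"] + neg
            }
        }
    }
    attr(tab, "subset") <- subset
    attr(tab, "total") <- sum(tab)
    tab
}

#' Chi-squared test of hemisphere-by-sign independence
#'
#' Pearson chi-squared test (df = 1) on a 2x2 sign-count table, optionally
#' with the Yates continuity correction. All margins must be positive for
#' the test to be defined.
#'
#' @param table 2x2 count matrix as from [signCountTable()].
#' @param correction `"none"` (plain Pearson, default) or `"yates"`.
#' @return list with `statistic`, `df`, `p` and `correction`.
#' @export
chiSquareTest <- function(table, correction = c("none", "yates")) {
    correction <- match.arg(correction)
    table <- as.matrix(table)
    if (!identical(dim(table), c(2L, 2L)))
        stop("a 2x2 table is required")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("zero margin: chi-squared test undefined")
    ct <- suppressWarnings(
        stats::chisq.test(table, correct = correction == "yates"))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value), correction = correction)
}

#' Chi-squared survival function
#'
#' Upper-tail probability of the chi-squared distribution; for df = 1 this
#' equals the two-sided normal tail of `sqrt(statistic)`.
#'
#' @param statistic chi-squared statistic, >= 0.
#' @param df degrees of freedom, >= 1.
#' @return upper-tail probability in (0, 1].
#' @export
chisqSF <- function(statistic, df = 1) {
    if (any(statistic < 0)) stop("statistic must be >= 0")
    if (any(df < 1)) stop("df must be >= 1")
    pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Left/right homologue correlation of coefficient maps
#'
#' Pearson correlation between the left-member and right-member coefficient
#' values across homologous pairs, per tissue subset. The pooled mode
#' concatenates the six indicator columns into one vector pair; the
#' per-indicator mode correlates each column separately. With
#' `adjust = "z"` (available when `x` is a [BaggedSolution-class]) the
#' bagged means are divided by their bootstrap standard deviations before
#' correlating (bootstrap-uncertainty-adjusted maps).
#'
#' @param x p-by-k coefficient matrix, [RidgeSolution-class] or
#'   [BaggedSolution-class].
#' @param map a `HomologueMap`.
#' @param subset tissue subset, see [signCountTable()].
#' @param perIndicator also return one correlation per indicator.
#' @param adjust `"none"` or `"z"`.
#' @return data.frame with columns `subset`, `indicator` (`"pooled"` or an
#'   indicator id), `r` and `n_pairs`.
#' @export
homologueCorrelation <- function(x, map, subset = "all_regions",
                                 perIndicator = FALSE,
                                 adjust = c("none", "z")) {
    adjust <- match.arg(adjust)
    vals <- if (is(x, "BaggedSolution")) {
        if (adjust == "z") {
            s <- x@sd
            s[s <= 1e-12] <- 1e-12
            x@mean / s
        } else x@mean
    } else if (is(x, "RidgeSolution")) coef(x) else as.matrix(x)
    pairs <- .subsetPairs(map, subset)
    if (nrow(pairs) < 3L)
        stop("fewer than 3 pairs in subset: ", subset)
    L <- vals[pairs$left, , drop = FALSE]
    R <- vals[pairs$right, , drop = FALSE]
    corSafe <- function(a, b) {
        if (sd(a) <= 1e-12 || sd(b) <= 1e-12)
            stop("zero-variance vector in homologue correlation")
        cor(a, b)
    }
    out <- data.frame(subset = subset, indicator = "pooled",
                      r = corSafe(as.vector(L), as.vector(R)),
                      n_pairs = nrow(pairs), stringsAsFactors = FALSE)
    if (perIndicator) {
        per <- data.frame(
            subset = subset, indicator = colnames(vals),
            r = vapply(seq_len(ncol(vals)),
                       function(j) corSafe(L[, j], R[, j]), numeric(1)),
            n_pairs = nrow(pairs), stringsAsFactors = FALSE)
        out <- rbind(out, per)
    }
    rownames(out) <- NULL
    out
}

#' Hemispheric-asymmetry summary
#'
#' Runs the full laterality battery: hemisphere-by-sign contingency tables
#' with Pearson chi-squared tests for the gray-matter and tract subsets, and
#' the homologue-correlation grid (pooled and per indicator) for every
#' tissue subset with at least 3 pairs, in both the uncertainty-adjusted and
#' plain flavors. When a subset has no significant associations, its
#' chi-squared entry is `NULL` (the test is refused rather than computed on
#' an empty table). Alongside the pooled (concatenated) correlation, the
#' mean of the per-indicator correlations is reported for comparison.
#'
#' @param bagged a [BaggedSolution-class].
#' @param report a [SignificanceReport-class].
#' @param map a `HomologueMap`.
#' @param correction chi-squared continuity correction, see
#'   [chiSquareTest()].
#' @return list of class `AsymmetrySummary` with elements `signTables`,
#'   `chiSquare`, `correlations` (uncertainty-adjusted),
#'   `correlationsPlain`, and `meanPerIndicatorR`.
#' @export
asymmetrySummary <- function(bagged, report, map, correction = "none") {
    subsets <- c("all_regions", "gray_matter", "cortical", "subcortical",
                 "tracts")
    nPairs <- vapply(subsets, function(s)
        nrow(tryCatch(.subsetPairs(map, s), error = function(e)
            data.frame())), integer(1))
    avail <- subsets[nPairs >= 3L]               # correlation needs >= 3 pairs
    testSubsets <- intersect(c("gray_matter", "tracts"),
                             subsets[nPairs >= 1L])

    signTables <- lapply(testSubsets, function(s)
        signCountTable(report, bagged, map, s))
    names(signTables) <- testSubsets
    chiSq <- lapply(signTables, function(tab) {
        if (sum(tab) == 0L || any(rowSums(tab) == 0) ||
            any(colSums(tab) == 0)) return(NULL)
        chiSquareTest(tab, correction)
    })

    corrGrid <- function(adj) {
        do.call(rbind, lapply(avail, function(s)
            homologueCorrelation(bagged, map, s, perIndicator = TRUE,
                                 adjust = adj)))
    }
    corrZ <- corrGrid("z")
    corrPlain <- corrGrid("none")
    meanPer <- vapply(split(corrZ[corrZ$indicator != "pooled", "r"],
                            corrZ[corrZ$indicator != "pooled", "subset"]),
                      mean, numeric(1))
    out <- list(signTables = signTables, chiSquare = chiSq,
                correlations = corrZ, correlationsPlain = corrPlain,
                meanPerIndicatorR = meanPer)
    class(out) <- "AsymmetrySummary"
    out
}

#' @export
print.AsymmetrySummary <- function(x, ...) {
    cat("AsymmetrySummary\n")
    for (s in names(x$signTables)) {
        cat("  subset", s, "sign counts (L/R x +/-):",
            paste(x$signTables[[s]], collapse = " "), "\n")
        cs <- x$chiSquare[[s]]
        if (is.null(cs)) {
            cat("    chi-squared test refused (no significant counts)\n")
        } else {
            cat(sprintf("    chi^2 = %.3f, df = %d, p = %.3f\n",
                        cs$statistic, cs$df, cs$p))
        }
    }
    pooled <- x$correlations[x$correlations$indicator == "pooled", ]
    for (i in seq_len(nrow(pooled)))
        cat(sprintf("  pooled homologue r (%s): %.3f (n_pairs = %d)\n",
                    pooled$subset[i], pooled$r[i], pooled$n_pairs[i]))
    invisible(x)
}
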
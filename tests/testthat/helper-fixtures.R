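# Small-atlas generator configuration used throughout the suite:
# 10 homologous pairs (6 cortical, 2 subcortical, 2 tract) + 2 midline
# features = 22 brain features.
tinyConfig <- function(nParticipants = 300L, ...) {
    cohortConfig(nParticipants = nParticipants, nCorticalPairs = 6L,
                 nSubcorticalPairs = 2L, nMidlineRegions = 1L,
                 nTractPairs = 2L, nMidlineTracts = 1L, ...)
}

# Continuous, fully linear cohort (no binning) for oracle comparisons.
continuousBins <- rep(0L, 6L)

# A hand-built atlas for pairing tests.
miniAtlas <- function() {
    data.frame(
        feature_id = c("a_L", "a_R", "b_L", "b_R", "c_L", "c_R",
                       "d_L", "d_R", "mid"),
        name = letters[c(1, 1, 2, 2, 3, 3, 4, 4, 5)],
        hemisphere = c("L", "R", "L", "R", "L", "R", "L", "R", "M"),
        tissue = c(rep("cortical", 4), rep("subcortical", 2),
                   rep("tract", 2), "subcortical"),
        homologue_id = c("a", "a", "b", "b", "c", "c", "d", "d", ""),
        stringsAsFactors = FALSE)
}

# Independent closed-form ridge oracle (normal equations, no shared code
# with the package solver paths beyond base solve()).
oracleRidge <- function(X, Y, alpha) {
    n <- nrow(X)
    solve(crossprod(X) / n + diag(alpha, ncol(X)), crossprod(X, Y) / n)
}
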
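.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

.readTSV <- function(path) {
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a cohort as TSV files
#'
#' The cohort is serialized as four TSV files with a shared
#' `participant_id` column (`features.tsv`, `ses.tsv`, `confounds.tsv`) plus
#' the atlas table (`atlas.tsv`) and, for simulated cohorts, a ground-truth
#' JSON sidecar (`truth.json`). All floats are written at full precision
#' with mandatory header rows.
#'
#' @param cohort an [SESCohort-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort()` the directory invisibly; `readCohort()` the
#'   reconstructed [SESCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pid <- colData(cohort)$participant_id
    .writeTSV(data.frame(participant_id = pid, brainFeatures(cohort),
                         check.names = FALSE),
              file.path(dir, "features.tsv"))
    .writeTSV(data.frame(participant_id = pid, sesTable(cohort),
                         check.names = FALSE),
              file.path(dir, "ses.tsv"))
    .writeTSV(data.frame(participant_id = pid, confoundTable(cohort),
                         check.names = FALSE),
              file.path(dir, "confounds.tsv"))
    .writeTSV(atlasTable(cohort), file.path(dir, "atlas.tsv"))
    truth <- cohortTruth(cohort)
    if (!is.null(truth))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             digits = NA, matrix = "rowmajor",
                             auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    feats <- .readTSV(file.path(dir, "features.tsv"))
    ses <- .readTSV(file.path(dir, "ses.tsv"))
    confounds <- .readTSV(file.path(dir, "confounds.tsv"))
    atlas <- .readTSV(file.path(dir, "atlas.tsv"))
    atlas$homologue_id[is.na(atlas$homologue_id)] <- ""
    for (tab in list(feats, ses, confounds))
        if (!"participant_id" %in% colnames(tab))
            stop("schema violation: participant_id column required in ",
                 "features/ses/confounds tables")
    if (!identical(feats$participant_id, ses$participant_id) ||
        !identical(feats$participant_id, confounds$participant_id))
        stop("schema violation: participant_id columns do not align")
    fm <- as.matrix(feats[, -1L, drop = FALSE])
    rownames(fm) <- feats$participant_id
    SESCohort(features = fm,
              ses = ses[, -1L, drop = FALSE],
              confounds = confounds[, -1L, drop = FALSE],
              atlas = atlas,
              participantId = feats$participant_id)
}

#' Write a region-by-term matrix as TSV
#'
#' @param terms matrix from [makeTermMatrix()].
#' @param path output file; first column `feature_id`, remaining columns the
#'   terms.
#' @return `writeTermMatrix()` the path invisibly; `readTermMatrix()` the
#'   matrix.
#' @export
writeTermMatrix <- function(terms, path) {
    .writeTSV(data.frame(feature_id = rownames(terms), terms,
                         check.names = FALSE), path)
    invisible(path)
}

#' @rdname writeTermMatrix
#' @export
readTermMatrix <- function(path) {
    df <- .readTSV(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$feature_id
    m
}

.coefTable <- function(mat) {
    data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
}

#' Serialize the significance report alongside the bagged estimates
#'
#' One row per (feature, indicator) cell: bagged mean, bootstrap sd,
#' percentile bounds, FWE-corrected p-value and significance flag.
#'
#' @param bagged a [BaggedSolution-class].
#' @param report a [SignificanceReport-class].
#' @return data.frame in long format.
#' @export
significanceTable <- function(bagged, report) {
    grid <- expand.grid(feature_id = rownames(bagged@mean),
                        indicator = colnames(bagged@mean),
                        stringsAsFactors = FALSE)
    grid$bagged_mean <- as.vector(bagged@mean)
    grid$sd <- as.vector(bagged@sd)
    grid$lo5 <- as.vector(bagged@lo5)
    grid$hi95 <- as.vector(bagged@hi95)
    grid$p_fwe <- as.vector(report@pFWE)
    grid$significant <- as.vector(report@significant)
    grid
}
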
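#' Construct an SESCohort from its component tables
#'
#' @param features numeric matrix of image-derived phenotypes, participants in
#'   rows and features in columns (column names = `feature_id`).
#' @param ses data.frame with the six raw SES indicator columns.
#' @param confounds data.frame of confound/covariate columns (head size, BMI,
#'   age, sex, fluid IQ, optionally handedness).
#' @param atlas data.frame with columns `feature_id`, `name`, `hemisphere`
#'   (L/R/M), `tissue` (cortical/subcortical/tract), `homologue_id` (empty for
#'   midline features).
#' @param participantId character vector of participant identifiers.
#' @param truth optional ground-truth list for simulated cohorts.
#' @param config optional generator configuration to record.
#' @return a validated [SESCohort-class] object.
#' @export
SESCohort <- function(features, ses, confounds, atlas,
                      participantId = rownames(features),
                      truth = NULL, config = NULL) {
    features <- as.matrix(features)
    if (is.null(participantId))
        participantId <- sprintf("P%05d", seq_len(nrow(features)))
    if (!identical(colnames(features), atlas$feature_id))
        stop("feature columns must match atlas$feature_id (same order)")
    cd <- DataFrame(participant_id = participantId, ses, confounds)
    rownames(cd) <- participantId
    se <- SummarizedExperiment(
        assays = list(features = t(features)),
        rowData = DataFrame(atlas),
        colData = cd,
        metadata = list(indicators = colnames(ses),
                        confounds = colnames(confounds),
                        truth = truth, config = config))
    rownames(se) <- atlas$feature_id
    new("SESCohort", se)
}

#' Accessors for SESCohort components
#'
#' `brainFeatures()` returns the participant-by-feature matrix,
#' `sesTable()` the raw SES indicator table, `confoundTable()` the
#' confound/covariate table, `atlasTable()` the atlas metadata and
#' `cohortTruth()` the simulation ground truth (`NULL` for real data).
#'
#' @param x an [SESCohort-class].
#' @return matrix or data.frame as described.
#' @export
brainFeatures <- function(x) t(assay(x, "features"))

#' @rdname brainFeatures
#' @export
sesTable <- function(x) {
    as.data.frame(colData(x)[, metadata(x)$indicators, drop = FALSE])
}

#' @rdname brainFeatures
#' @export
confoundTable <- function(x) {
    as.data.frame(colData(x)[, metadata(x)$confounds, drop = FALSE])
}

#' @rdname brainFeatures
#' @export
atlasTable <- function(x) as.data.frame(rowData(x))

#' @rdname brainFeatures
#' @export
cohortTruth <- function(x) metadata(x)$truth

setMethod("show", "SESCohort", function(object) {
    rd <- rowData(object)
    cat("SESCohort:", ncol(object), "participants,", nrow(object),
        "brain features\n")
    cat("  tissue: ", paste(sprintf("%s=%d", names(table(rd$tissue)),
                                    table(rd$tissue)), collapse = ", "), "\n")
    cat("  indicators:", paste(metadata(object)$indicators, collapse = ", "),
        "\n")
    cat("  confounds: ", paste(metadata(object)$confounds, collapse = ", "),
        "\n")
    if (!is.null(metadata(object)$truth))
        cat("  simulated cohort with ground truth attached\n")
})
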
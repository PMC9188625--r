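#' Configuration of the end-to-end pipeline
#'
#' Fully serializable run configuration: a run is reproducible from its
#' config alone. Either `inputDir` (cohort TSVs as written by
#' [writeCohort()]) or `generator` (a [cohortConfig()]) must provide the
#' data.
#'
#' @param generator [cohortConfig()] for a simulated cohort, or `NULL`.
#' @param inputDir directory with cohort TSVs, or `NULL`.
#' @param ridge a [ridgeConfig()].
#' @param B bootstrap resamples.
#' @param R permutations.
#' @param threshold FWE significance threshold.
#' @param nTerms term-matrix size for the annotation stage (0 disables
#'   annotation).
#' @param includeHandedness include handedness as covariate.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param outDir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(generator = cohortConfig(), inputDir = NULL,
                           ridge = ridgeConfig(), B = 100L, R = 1000L,
                           threshold = 0.001, nTerms = 20L,
                           includeHandedness = FALSE, seed = 1L,
                           outDir = tempfile("ses_run_")) {
    if (is.null(generator) && is.null(inputDir))
        stop("either a generator config or an input directory is required")
    cfg <- list(generator = generator, inputDir = inputDir, ridge = ridge,
                B = as.integer(B), R = as.integer(R),
                threshold = as.numeric(threshold), nTerms = as.integer(nTerms),
                includeHandedness = isTRUE(includeHandedness),
                seed = as.integer(seed), outDir = outDir)
    if (cfg$B < 2L) stop("B must be >= 2")
    if (cfg$R < 1L) stop("R must be >= 1")
    if (cfg$threshold <= 0 || cfg$threshold >= 1)
        stop("threshold must lie in (0, 1)")
    class(cfg) <- "PipelineConfig"
    cfg
}

.stageSeed <- function(seed, stage) {
    # deterministic per-stage seeds, kept within 32-bit integer range
    (as.integer(seed) * 7L + stage * 131L) %% 2147483000L
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate/load -> preprocess (orient, deconfound, z-score) ->
#' fit -> bootstrap bagging -> permutation FWE inference -> laterality ->
#' SES structure -> annotation. Every stage output is written under
#' `outDir` with stable filenames, and a manifest records the config, the
#' per-stage seeds and wall times. Rerunning with an identical config
#' reproduces identical numerical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage objects and the
#'   summary (also written as `summary.json`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    times <- list()
    clock <- function(expr) {
        t0 <- proc.time()[["elapsed"]]
        val <- force(expr)
        list(val = val, secs = proc.time()[["elapsed"]] - t0)
    }

    st <- clock({
        if (!is.null(config$inputDir)) readCohort(config$inputDir)
        else {
            gen <- config$generator
            gen$seed <- .stageSeed(config$seed, 1L)
            simulateCohort(gen)
        }
    })
    cohort <- st$val
    times$cohort <- st$secs
    writeCohort(cohort, file.path(outDir, "cohort"))

    st <- clock(preprocessCohort(cohort,
                                 includeHandedness = config$includeHandedness))
    frame <- st$val
    times$preprocess <- st$secs

    st <- clock(fitRidge(frame, config = config$ridge))
    fit <- st$val
    times$fit <- st$secs
    .writeTSV(.coefTable(coef(fit)), file.path(outDir, "coefficients.tsv"))

    st <- clock(bootstrapBag(frame, config$ridge, B = config$B,
                             seed = .stageSeed(config$seed, 2L)))
    bagged <- st$val
    times$bootstrap <- st$secs
    .writeTSV(.coefTable(bagged@mean), file.path(outDir, "bagged_mean.tsv"))

    st <- clock(permutationNull(frame, config$ridge, R = config$R,
                                seed = .stageSeed(config$seed, 3L)))
    null <- st$val
    times$permutation <- st$secs

    report <- fwePvalues(bagged, null, threshold = config$threshold)
    .writeTSV(significanceTable(bagged, report),
              file.path(outDir, "significance.tsv"))

    st <- clock({
        map <- pairHomologues(atlasTable(cohort))
        asymmetrySummary(bagged, report, map)
    })
    asym <- st$val
    times$laterality <- st$secs
    .writeTSV(asym$correlations,
              file.path(outDir, "homologue_correlations.tsv"))

    st <- clock({
        sesZ <- frame@Y
        list(correlation = pairwiseCorrelation(sesZ),
             pca = pcaDecompose(sesZ),
             ageAssoc = univariateAssoc(sesZ, confoundTable(cohort)$age),
             sexAssoc = univariateAssoc(sesZ, confoundTable(cohort)$sex))
    })
    struct <- st$val
    times$structure <- st$secs
    .writeTSV(data.frame(indicator = rownames(struct$correlation),
                         struct$correlation, check.names = FALSE),
              file.path(outDir, "ses_correlation.tsv"))

    profiles <- NULL
    if (config$nTerms > 0L) {
        st <- clock({
            terms <- makeTermMatrix(atlasTable(cohort), config$nTerms,
                                    seed = .stageSeed(config$seed, 4L))
            grayMean <- bagged@mean[rownames(terms), , drop = FALSE]
            prof <- profileTerms(grayMean, terms)
            prof[order(-abs(prof$r)), ]
        })
        profiles <- st$val
        times$annotation <- st$secs
        .writeTSV(profiles, file.path(outDir, "term_profiles.tsv"))
    }

    nSig <- sum(significantCells(report))
    chiOut <- lapply(asym$chiSquare, function(cs)
        if (is.null(cs)) NULL else
            cs[c("statistic", "df", "p", "correction")])
    pooledR <- asym$correlations[
        asym$correlations$indicator == "pooled" &
        asym$correlations$subset == "all_regions", "r"]
    summary <- list(
        n_participants = ncol(cohort),
        n_features = nrow(cohort),
        alpha = config$ridge$alpha,
        B = config$B, R = config$R, threshold = config$threshold,
        n_significant_cells = nSig,
        chi_square = chiOut,
        pooled_homologue_r = pooledR,
        pca_explained_variance_ratio =
            as.numeric(struct$pca$explainedVarianceRatio),
        seed = config$seed)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    declass <- function(x) if (is.list(x)) lapply(unclass(x), declass) else x
    manifest <- list(
        config = declass(config),
        stage_seconds = times,
        stage_seeds = lapply(stats::setNames(1:4, c(
            "cohort", "bootstrap", "permutation", "terms")),
            function(s) .stageSeed(config$seed, s)),
        config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")

    invisible(list(cohort = cohort, frame = frame, fit = fit,
                   bagged = bagged, null = null, report = report,
                   asymmetry = asym, structure = struct,
                   profiles = profiles, summary = summary,
                   outDir = outDir))
}
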
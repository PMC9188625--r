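.INDICATORS <- c("income", "education_years", "degree", "neighborhood_level",
                 "vehicle_count", "job")

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure the downstream analysis assumes: six SES
#' indicators sharing a single latent factor (all pairwise correlations kept
#' below 0.5 by the default loadings), brain features contaminated by
#' head-size/BMI confounds, and a planted coefficient pattern in which a
#' configurable fraction of homologous region/tract pairs carries mirrored
#' effects (positive left, negative right).
#'
#' @param nParticipants cohort size.
#' @param nCorticalPairs,nSubcorticalPairs,nTractPairs numbers of homologous
#'   left/right feature pairs per tissue class.
#' @param nMidlineRegions,nMidlineTracts midline (unpaired) feature counts;
#'   midline features carry effects but never enter laterality pairing.
#' @param sesLoadings loadings of the six indicators on the shared latent
#'   factor, in the order income, education years, degree, neighborhood level,
#'   vehicle count, job.
#' @param sesNoiseSD per-indicator unique noise scale in the factor model.
#' @param ordinalBins per-indicator band counts: 0 keeps the indicator
#'   continuous, 2 gives a binary (median-split) encoding, larger values give
#'   quantile-binned ordinal bands.
#' @param effectScale magnitude of each planted standardized effect.
#' @param asymmetryFraction fraction of homologous pairs (all of which carry
#'   effects) that receive the mirrored left-positive/right-negative pattern;
#'   the remaining pairs carry a one-sided effect with random hemisphere and
#'   per-indicator random sign.
#' @param confoundEffectSD scale of the head-size/BMI loadings onto brain
#'   features.
#' @param outcomeNoiseSD master scale of the non-brain part of each indicator
#'   (latent factor plus unique noise); 0 makes the indicators an exact linear
#'   function of the brain features.
#' @param confoundOnSES if `TRUE`, head size and BMI additionally leak into
#'   the SES indicators (deconfounding stress test); default `FALSE`.
#' @param seed integer RNG seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return a validated list of class `GeneratorConfig`.
#' @details Confound/covariate marginals: head size, BMI and fluid IQ are
#'   standard normal (standardized units), age is uniform on 40-70 years,
#'   sex is Bernoulli(0.52) coded 0/1, handedness Bernoulli(0.9) (1 =
#'   right-handed). The raw neighborhood indicator is stored in deprivation
#'   direction (higher = more deprived) so the orientation step has real work
#'   to do; the binary job indicator is stored 1 = knowledge worker.
#' @export
cohortConfig <- function(nParticipants = 5000L,
                         nCorticalPairs = 20L,
                         nSubcorticalPairs = 5L,
                         nMidlineRegions = 2L,
                         nTractPairs = 3L,
                         nMidlineTracts = 1L,
                         sesLoadings = c(0.6, 0.6, 0.5, 0.5, 0.4, 0.4),
                         sesNoiseSD = 1,
                         ordinalBins = c(5L, 0L, 5L, 0L, 4L, 2L),
                         effectScale = 0.1,
                         asymmetryFraction = 0.5,
                         confoundEffectSD = 0.3,
                         outcomeNoiseSD = 1,
                         confoundOnSES = FALSE,
                         seed = 1L) {
    cfg <- list(nParticipants = as.integer(nParticipants),
                nCorticalPairs = as.integer(nCorticalPairs),
                nSubcorticalPairs = as.integer(nSubcorticalPairs),
                nMidlineRegions = as.integer(nMidlineRegions),
                nTractPairs = as.integer(nTractPairs),
                nMidlineTracts = as.integer(nMidlineTracts),
                sesLoadings = as.numeric(sesLoadings),
                sesNoiseSD = as.numeric(sesNoiseSD),
                ordinalBins = as.integer(ordinalBins),
                effectScale = as.numeric(effectScale),
                asymmetryFraction = as.numeric(asymmetryFraction),
                confoundEffectSD = as.numeric(confoundEffectSD),
                outcomeNoiseSD = as.numeric(outcomeNoiseSD),
                confoundOnSES = isTRUE(confoundOnSES),
                seed = as.integer(seed))
    counts <- c(cfg$nCorticalPairs, cfg$nSubcorticalPairs, cfg$nMidlineRegions,
                cfg$nTractPairs, cfg$nMidlineTracts)
    if (any(counts < 0L)) stop("feature counts must be >= 0")
    if (sum(counts * c(2L, 2L, 1L, 2L, 1L)) < 1L)
        stop("total feature count must be >= 1")
    if (cfg$nParticipants <= 0L) stop("nParticipants must be positive")
    if (cfg$asymmetryFraction < 0 || cfg$asymmetryFraction > 1)
        stop("asymmetryFraction must lie in [0, 1]")
    if (length(cfg$sesLoadings) != 6L || length(cfg$ordinalBins) != 6L)
        stop("sesLoadings and ordinalBins must have 6 entries")
    if (any(cfg$ordinalBins == 1L))
        stop("ordinalBins entries must be 0 (continuous) or >= 2")
    class(cfg) <- "GeneratorConfig"
    cfg
}

.buildAtlas <- function(cfg) {
    rows <- list()
    addPairs <- function(n, prefix, tissue, label) {
        if (n < 1L) return(NULL)
        do.call(rbind, lapply(seq_len(n), function(i) {
            hid <- sprintf("%s_%03d", prefix, i)
            data.frame(
                feature_id = sprintf("%s_%s_%03d", prefix, c("L", "R"), i),
                name = sprintf("%s %d (%s)", label, i, c("left", "right")),
                hemisphere = c("L", "R"), tissue = tissue,
                homologue_id = hid, stringsAsFactors = FALSE)
        }))
    }
    addMid <- function(n, prefix, tissue, label) {
        if (n < 1L) return(NULL)
        data.frame(feature_id = sprintf("%s_M_%03d", prefix, seq_len(n)),
                   name = sprintf("%s %d (midline)", label, seq_len(n)),
                   hemisphere = "M", tissue = tissue, homologue_id = "",
                   stringsAsFactors = FALSE)
    }
    atlas <- rbind(
        addPairs(cfg$nCorticalPairs, "ctx", "cortical", "cortical region"),
        addMid(cfg$nMidlineRegions, "sub", "subcortical", "midline region"),
        addPairs(cfg$nSubcorticalPairs, "sub", "subcortical",
                 "subcortical region"),
        addPairs(cfg$nTractPairs, "trt", "tract", "fiber tract"),
        addMid(cfg$nMidlineTracts, "trt", "tract", "midline tract"))
    rownames(atlas) <- NULL
    atlas
}

.plantTruth <- function(cfg, atlas) {
    p <- nrow(atlas)
    W <- matrix(0, p, 6L, dimnames = list(atlas$feature_id, .INDICATORS))
    pairIds <- unique(atlas$homologue_id[atlas$homologue_id != ""])
    nMirror <- round(cfg$asymmetryFraction * length(pairIds))
    mirrorIds <- if (nMirror > 0L) sample(pairIds, nMirror) else character(0)
    e <- cfg$effectScale
    for (pid in pairIds) {
        li <- which(atlas$homologue_id == pid & atlas$hemisphere == "L")
        ri <- which(atlas$homologue_id == pid & atlas$hemisphere == "R")
        if (pid %in% mirrorIds) {
            W[li, ] <- e
            W[ri, ] <- -e
        } else {
            side <- if (runif(1) < 0.5) li else ri
            W[side, ] <- e * sample(c(-1, 1), 6L, replace = TRUE)
        }
    }
    for (mi in which(atlas$hemisphere == "M"))
        W[mi, ] <- e * sample(c(-1, 1), 6L, replace = TRUE)
    list(trueCoefficients = W,
         latentLoadings = stats::setNames(cfg$sesLoadings, .INDICATORS),
         asymmetricPairIds = sort(mirrorIds),
         effectPairIds = pairIds)
}

.quantileBin <- function(x, nBins) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                          names = FALSE))
    as.numeric(cut(x, breaks = br, labels = FALSE, include.lowest = TRUE))
}

#' Generate a synthetic cohort with planted lateralized effects
#'
#' Draws brain features as confound contributions plus standard-normal noise,
#' and SES indicators as a shared latent factor plus a brain-feature signal
#' `Y = X W_true + noise`, then applies the configured ordinal/binary
#' encodings. Ground truth (planted coefficients, confound loadings, mirrored
#' pair identifiers) is attached to the returned cohort.
#'
#' @param config a [cohortConfig()] object.
#' @return an [SESCohort-class] with `cohortTruth()` populated.
#' @examples
#' coh <- simulateCohort(cohortConfig(nParticipants = 200, seed = 7))
#' dim(brainFeatures(coh))
#' @export
simulateCohort <- function(config = cohortConfig()) {
    if (!inherits(config, "GeneratorConfig"))
        config <- do.call(cohortConfig, config)
    set.seed(config$seed)
    atlas <- .buildAtlas(config)
    p <- nrow(atlas)
    n <- config$nParticipants
    truth <- .plantTruth(config, atlas)

    Gamma <- matrix(rnorm(p * 2L, sd = config$confoundEffectSD), p, 2L,
                    dimnames = list(atlas$feature_id, c("head_size", "bmi")))
    truth$confoundLoadings <- Gamma

    headSize <- rnorm(n)
    bmi <- rnorm(n)
    age <- runif(n, 40, 70)
    sex <- rbinom(n, 1L, 0.52)
    iq <- rnorm(n)
    handedness <- rbinom(n, 1L, 0.9)

    X <- cbind(headSize, bmi) %*% t(Gamma) +
        matrix(rnorm(n * p), n, p)
    colnames(X) <- atlas$feature_id

    g <- rnorm(n)
    eps <- matrix(rnorm(n * 6L), n, 6L)
    Ycont <- X %*% truth$trueCoefficients +
        config$outcomeNoiseSD *
        (outer(g, config$sesLoadings) + config$sesNoiseSD * eps)
    colnames(Ycont) <- .INDICATORS
    if (config$confoundOnSES)
        Ycont <- Ycont + 0.2 * (headSize + bmi)

    ses <- as.data.frame(Ycont)
    for (j in seq_len(6L)) {
        b <- config$ordinalBins[j]
        if (b >= 2L) {
            binned <- .quantileBin(Ycont[, j], b)
            if (b == 2L) binned <- binned - 1  # binary coded 0/1
            ses[[j]] <- binned
        }
    }
    # raw neighborhood is stored in deprivation direction; the orientation
    # step of the pipeline inverts it back so higher = higher SES
    ses$neighborhood_level <- -ses$neighborhood_level

    confounds <- data.frame(head_size = headSize, bmi = bmi, age = age,
                            sex = sex, iq = iq, handedness = handedness)
    SESCohort(features = X, ses = ses, confounds = confounds, atlas = atlas,
              participantId = sprintf("P%05d", seq_len(n)),
              truth = truth, config = config)
}

#' Generate a region-by-term association matrix fixture
#'
#' Produces a gray-matter (cortical + subcortical) region-by-term matrix with
#' values in [0, 1], emulating meta-analytic term-association exports. One
#' column can be constructed collinear with a designated coefficient map so
#' annotation recovery can be tested against ground truth.
#'
#' @param atlas atlas data.frame as in [atlasTable()].
#' @param nTerms number of term columns (>= 1).
#' @param seed integer RNG seed.
#' @param collinearWith optional named numeric vector over gray-matter
#'   feature ids; when supplied, the first term column is an affine rescaling
#'   of it into [0, 1] (correlation exactly 1) and is labelled `"planted"`.
#' @return numeric matrix, gray-matter regions (rownames = feature_id) by
#'   terms.
#' @export
makeTermMatrix <- function(atlas, nTerms, seed = 1L, collinearWith = NULL) {
    if (nTerms < 1L) stop("nTerms must be >= 1")
    gray <- atlas$feature_id[atlas$tissue %in% c("cortical", "subcortical")]
    if (!length(gray)) stop("atlas has zero gray-matter features")
    set.seed(as.integer(seed))
    M <- matrix(runif(length(gray) * nTerms), length(gray), nTerms,
                dimnames = list(gray, sprintf("term_%03d", seq_len(nTerms))))
    if (!is.null(collinearWith)) {
        if (!all(gray %in% names(collinearWith)))
            stop("collinearWith must cover all gray-matter feature ids")
        v <- collinearWith[gray]
        rng <- range(v)
        if (diff(rng) < 1e-12)
            stop("collinearWith map is constant; cannot rescale to [0, 1]")
        M[, 1L] <- (v - rng[1L]) / diff(rng)
        colnames(M)[1L] <- "planted"
    }
    M
}
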
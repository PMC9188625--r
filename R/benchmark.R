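.builtinModels <- function(config, knnK) {
    list(
        ridge = function(Xtr, Ytr) {
            fit <- .fitRidgeCore(Xtr, Ytr, config)
            function(Xte) predict(fit, Xte)
        },
        ols = function(Xtr, Ytr) {
            cfg <- config
            cfg$alpha <- 0
            fit <- .fitRidgeCore(Xtr, Ytr, cfg)
            function(Xte) predict(fit, Xte)
        },
        knn = function(Xtr, Ytr) {
            if (!requireNamespace("caret", quietly = TRUE))
                stop("the 'caret' package is required for the knn learner")
            fits <- lapply(seq_len(ncol(Ytr)), function(j)
                caret::knnreg(Xtr, Ytr[, j], k = knnK))
            function(Xte) {
                out <- vapply(fits, function(f) predict(f, Xte),
                              numeric(nrow(Xte)))
                colnames(out) <- colnames(Ytr)
                out
            }
        })
}

#' Cross-validated out-of-sample benchmark
#'
#' Seeded, shuffled k-fold cross-validation of one or more learners on a
#' cohort. All preprocessing parameters (nuisance residualization, age
#' centering, standardization) are learned on the training folds only and
#' applied unchanged to the held-out fold, so the reported metrics are honest
#' out-of-sample estimates. Fold-wise metric tables are averaged elementwise.
#'
#' @param cohort an [SESCohort-class].
#' @param models character vector naming built-in learners (`"ridge"`,
#'   `"ols"`, `"knn"`) and/or a named list of custom learners; a custom
#'   learner is `function(Xtr, Ytr)` returning a prediction
#'   `function(Xte)`.
#' @param nFolds number of folds (>= 2).
#' @param seed RNG seed for the fold shuffle.
#' @param config [ridgeConfig()] for the ridge/ols built-ins.
#' @param knnK neighbor count for the knn built-in.
#' @param orientation,includeHandedness,nuisance as in [preprocessCohort()].
#' @return named list of metric data.frames (see [scoreMetrics()]), one per
#'   model.
#' @export
crossvalBenchmark <- function(cohort, models = c("ridge", "ols", "knn"),
                              nFolds = 5L, seed = 1L,
                              config = ridgeConfig(), knnK = 10L,
                              orientation = defaultOrientationMap(),
                              includeHandedness = FALSE,
                              nuisance = c("head_size", "bmi")) {
    if (nFolds < 2L) stop("nFolds must be >= 2")
    builtins <- .builtinModels(config, knnK)
    if (is.character(models)) {
        unknown <- setdiff(models, names(builtins))
        if (length(unknown))
            stop("unknown model_spec: ", paste(unknown, collapse = ", "))
        models <- builtins[models]
    } else if (is.list(models)) {
        models <- lapply(models, function(m) {
            if (is.character(m)) {
                if (!m %in% names(builtins))
                    stop("unknown model_spec: ", m)
                builtins[[m]]
            } else m
        })
    }
    feats <- brainFeatures(cohort)
    conf <- confoundTable(cohort)
    Yor <- as.matrix(orientIndicators(sesTable(cohort), orientation))
    n <- nrow(feats)
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(nFolds), n))

    foldData <- lapply(seq_len(nFolds), function(f) {
        tr <- fold != f
        te <- !tr
        nuis <- as.matrix(conf[, nuisance, drop = FALSE])
        resTr <- residualize(feats[tr, , drop = FALSE],
                             nuis[tr, , drop = FALSE])
        resTe <- residualize(feats[te, , drop = FALSE],
                             nuis[te, , drop = FALSE],
                             coefficients = attr(resTr, "coefficients"))
        covTr <- buildCovariates(conf$age[tr], conf$sex[tr], conf$iq[tr],
                                 if (includeHandedness) conf$handedness[tr])
        covTe <- buildCovariates(conf$age[te], conf$sex[te], conf$iq[te],
                                 if (includeHandedness) conf$handedness[te],
                                 ageCenter = attr(covTr, "ageCenter"))
        keep <- setdiff(colnames(covTr), attr(covTr, "constant"))
        sx <- standardize(cbind(resTr, covTr[, keep, drop = FALSE]))
        sy <- standardize(Yor[tr, , drop = FALSE])
        list(Xtr = sx$values, Ytr = sy$values,
             Xte = applyStandardization(
                 cbind(resTe, covTe[, keep, drop = FALSE]), sx),
             Yte = applyStandardization(Yor[te, , drop = FALSE], sy))
    })

    lapply(models, function(learner) {
        tabs <- lapply(foldData, function(d) {
            pred <- learner(d$Xtr, d$Ytr)
            scoreMetrics(d$Yte, pred(d$Xte))
        })
        avg <- tabs[[1L]]
        num <- vapply(tabs, function(t) as.matrix(t[, -1L]),
                      matrix(0, nrow(avg), ncol(avg) - 1L))
        avg[, -1L] <- apply(num, c(1, 2), mean)
        avg
    })
}
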
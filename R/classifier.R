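#' Module-median feature scores
#'
#' Collapses an expression matrix to one feature per gene module: the
#' per-sample median expression over the module's genes present in the
#' input. By default genes are first z-scored across the cohort
#' (`standardise = TRUE`), which makes the medians portable across
#' platforms with different intensity scales. Modules with gene coverage
#' below `minCoverage` are flagged unusable and get NA scores.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @param modules a [GeneModuleSet-class].
#' @param minCoverage minimum fraction of a module's genes that must be
#'   present (default 0.5).
#' @param standardise z-score each gene across samples before taking
#'   medians (default TRUE).
#' @return a [ModuleScoreMatrix-class] (samples x modules).
#' @export
moduleMedians <- function(x, modules, minCoverage = 0.5, standardise = TRUE) {
    stopifnot(is(modules, "GeneModuleSet"))
    m <- .getExprs(x)
    mods <- moduleList(modules)
    if (!length(mods)) stop("the module set is empty")
    if (!length(intersect(unlist(mods), rownames(m))))
        stop("no overlap between module genes and matrix genes")

    if (standardise) {
        mu <- rowMeans(m)
        sd <- apply(m, 1, stats::sd)
        m <- (m - mu) / ifelse(sd > 0, sd, 1)
    }
    scores <- matrix(NA_real_, ncol(m), length(mods),
                     dimnames = list(colnames(m), names(mods)))
    coverage <- numeric(length(mods))
    names(coverage) <- names(mods)
    for (j in seq_along(mods)) {
        present <- intersect(mods[[j]], rownames(m))
        coverage[j] <- length(present) / length(mods[[j]])
        if (length(present))
            scores[, j] <- apply(m[present, , drop = FALSE], 2, stats::median)
    }
    usable <- coverage >= minCoverage
    if (!any(usable))
        stop("no module reaches the coverage floor of ", minCoverage)
    scores[, !usable] <- NA_real_
    new("ModuleScoreMatrix", scores = scores, coverage = coverage,
        usable = unname(usable), minCoverage = minCoverage)
}

.boosterFromRaw <- function(raw) xgboost::xgb.load.raw(raw)

.trainBooster <- function(xmat, yint, nClass, params, nrounds) {
    d <- xgboost::xgb.DMatrix(data = xmat, label = yint, nthread = 1)
    xgboost::xgb.train(
        params = c(list(objective = "multi:softprob", num_class = nClass,
                        nthread = 1), params),
        data = d, nrounds = nrounds, verbose = 0)
}

#' Train the gradient-boosted subtype classifier
#'
#' Fits a multiclass gradient-boosted decision-tree ensemble (softmax
#' objective) on module-median scores, with stratified k-fold
#' cross-validation recording per-fold accuracy and per-class one-vs-rest
#' ROC AUC, then refits on all samples. Training is deterministic for a
#' fixed seed (single thread, no subsampling). Default hyperparameters:
#' depth-3 trees, 200 boosting rounds, learning rate 0.1.
#'
#' @param scores a [ModuleScoreMatrix-class] (or samples x features matrix).
#' @param labels subtype label per sample; every class needs at least
#'   `folds` samples.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @param maxDepth,eta,nrounds booster hyperparameters.
#' @return a [SubtypeModel-class]. When `scores` is a `ModuleScoreMatrix`
#'   derived from a [GeneModuleSet-class] pass that set via `moduleSet` so
#'   the model can rebuild features from raw expression.
#' @param moduleSet the [GeneModuleSet-class] defining the features
#'   (required for [predictSubtypes()] on expression input).
#' @param minCoverage coverage floor stored for prediction-time scoring.
#' @importFrom pROC roc auc
#' @export
trainSubtypeModel <- function(scores, labels, folds = 5L, seed = 1L,
                              maxDepth = 3L, eta = 0.1, nrounds = 200L,
                              moduleSet = NULL, minCoverage = 0.5) {
    sm <- if (is(scores, "ModuleScoreMatrix")) scoreMatrix(scores) else as.matrix(scores)
    labels <- factor(labels)
    classes <- levels(labels)
    stopifnot(nrow(sm) == length(labels))
    tab <- table(labels)
    if (any(tab < folds))
        stop("class(es) with fewer than ", folds, " samples: ",
             paste(names(tab)[tab < folds], collapse = ", "))

    featureMedians <- apply(sm, 2, stats::median, na.rm = TRUE)
    featureMedians[!is.finite(featureMedians)] <- 0
    for (j in seq_len(ncol(sm)))
        sm[is.na(sm[, j]), j] <- featureMedians[j]

    params <- list(max_depth = maxDepth, eta = eta)
    yint <- as.integer(labels) - 1L

    ## stratified fold assignment
    set.seed(seed)
    fold <- integer(nrow(sm))
    for (cls in classes) {
        idx <- which(labels == cls)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }

    acc <- numeric(folds)
    aucs <- matrix(NA_real_, folds, length(classes),
                   dimnames = list(NULL, classes))
    for (f in seq_len(folds)) {
        tr <- fold != f
        bst <- .trainBooster(sm[tr, , drop = FALSE], yint[tr],
                             length(classes), params, nrounds)
        prob <- predict(bst, sm[!tr, , drop = FALSE])
        pred <- max.col(prob, ties.method = "first")
        acc[f] <- mean(pred == as.integer(labels)[!tr])
        for (ci in seq_along(classes)) {
            resp <- as.integer(labels[!tr] == classes[ci])
            if (length(unique(resp)) == 2)
                aucs[f, ci] <- as.numeric(pROC::auc(pROC::roc(
                    resp, prob[, ci], quiet = TRUE, direction = "<",
                    levels = c(0, 1))))
        }
    }

    final <- .trainBooster(sm, yint, length(classes), params, nrounds)
    ms <- if (is.null(moduleSet))
        new("GeneModuleSet",
            modules = as.list(structure(colnames(sm), names = colnames(sm))),
            unassigned = character(0), provenance = list(source = "features"))
    else moduleSet
    new("SubtypeModel",
        moduleSet = ms,
        boosterRaw = xgboost::xgb.save.raw(final, raw_format = "json"),
        classes = classes,
        cvMetrics = data.frame(fold = seq_len(folds), accuracy = acc),
        cvAUC = aucs,
        featureMedians = featureMedians,
        config = list(folds = as.integer(folds), seed = as.integer(seed),
                      maxDepth = as.integer(maxDepth), eta = eta,
                      nrounds = as.integer(nrounds),
                      features = colnames(sm), minCoverage = minCoverage))
}

#' Predict subtypes for new samples
#'
#' Scores the cohort with the model's frozen module definitions, imputes
#' modules missing (coverage below the floor) with the training median of
#' that module score, and returns per-sample class probabilities and the
#' argmax label (ties broken by class order). At least 80% of the model's
#' modules must reach the coverage floor.
#'
#' @param model a [SubtypeModel-class].
#' @param x a [RectalCohort-class], genes x samples matrix, or a
#'   [ModuleScoreMatrix-class] already on the model's features.
#' @return data.frame with `sample`, `label` and one probability column per
#'   class (rows sum to 1).
#' @export
predictSubtypes <- function(model, x) {
    stopifnot(is(model, "SubtypeModel"))
    feats <- model@config$features
    if (is(x, "ModuleScoreMatrix")) {
        sm <- scoreMatrix(x)[, feats, drop = FALSE]
    } else {
        msm <- moduleMedians(x, moduleSet(model),
                             minCoverage = model@config$minCoverage %||% 0.5)
        sm <- scoreMatrix(msm)[, feats, drop = FALSE]
        usable <- msm@usable[match(feats, colnames(scoreMatrix(msm)))]
        if (mean(usable) < 0.8)
            stop("module coverage below the floor for: ",
                 paste(feats[!usable], collapse = ", "),
                 " (more than 20% of modules unusable)")
    }
    for (j in seq_along(feats))
        sm[is.na(sm[, j]), j] <- model@featureMedians[feats[j]]

    bst <- .boosterFromRaw(model@boosterRaw)
    prob <- predict(bst, sm)
    prob <- prob / rowSums(prob)   # exact simplex (booster sums are float32)
    colnames(prob) <- model@classes
    lab <- model@classes[max.col(prob, ties.method = "first")]
    out <- data.frame(sample = rownames(sm), label = lab, prob,
                      check.names = FALSE, row.names = NULL)
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise / deserialise a SubtypeModel
#'
#' Writes a single JSON archive holding the model metadata (classes, module
#' definitions, CV metrics, training configuration, feature medians)
#' together with the portable JSON dump of the boosted ensemble, and reads
#' it back. The round trip is exact: the restored model holds a
#' byte-identical booster and produces identical predictions.
#'
#' @param model a [SubtypeModel-class].
#' @param path archive path (conventionally `.json`).
#' @return `saveSubtypeModel`: `path`, invisibly; `readSubtypeModel`: the
#'   restored [SubtypeModel-class].
#' @export
saveSubtypeModel <- function(model, path) {
    stopifnot(is(model, "SubtypeModel"))
    ms <- moduleSet(model)
    prov <- provenance(ms)
    prov <- prov[!vapply(prov, is.data.frame, logical(1))]
    payload <- list(
        format = "RectalSubtypes/SubtypeModel/1",
        classes = model@classes,
        cvMetrics = model@cvMetrics,
        cvAUC = as.data.frame(model@cvAUC),
        featureMedians = as.list(model@featureMedians),
        config = model@config,
        modules = moduleList(ms),
        unassigned = unassignedGenes(ms),
        provenance = prov,
        booster = rawToChar(model@boosterRaw))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveSubtypeModel
#' @export
readSubtypeModel <- function(path) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(p$format, "RectalSubtypes/SubtypeModel/1"))
        stop("not a SubtypeModel archive: ", path)
    mods <- lapply(p$modules, as.character)
    ms <- new("GeneModuleSet", modules = mods,
              unassigned = as.character(p$unassigned),
              provenance = as.list(p$provenance))
    cfg <- as.list(p$config)
    cfg$features <- as.character(cfg$features)
    new("SubtypeModel",
        moduleSet = ms,
        boosterRaw = charToRaw(p$booster),
        classes = as.character(p$classes),
        cvMetrics = as.data.frame(p$cvMetrics),
        cvAUC = as.matrix(p$cvAUC),
        featureMedians = unlist(p$featureMedians),
        config = cfg)
}
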
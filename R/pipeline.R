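#' Build a validated end-to-end run configuration
#'
#' Collects every knob of the discovery pipeline in one list: the synthetic
#' cohort (or a path/object supplying real data), stage toggles, and the
#' parameters of each stage. A single global `seed` is fanned out to the
#' stochastic stages by fixed offsets (cohort = seed, consensus resampling =
#' seed + 1000, classifier folds = seed + 2000), so one integer reproduces
#' the whole run.
#'
#' @param outDir directory for artifacts.
#' @param seed global seed.
#' @param cohort a [RectalCohort-class], a path to an expression TSV, or
#'   NULL to simulate from `cohortConfig`.
#' @param cohortConfig a [cohortConfig()] used when `cohort` is NULL.
#' @param doPreprocess,doConsensus,doModules,doTrain stage toggles.
#' @param kRange,nResamples,sampleFrac,linkage,dropFrac,minDelta consensus
#'   stage parameters (see [consensusCluster()]).
#' @param fdrAlpha,beta,connectivityCutoff,kMin,kMax,minSize,moduleMethod,
#'   stabilityFrac module stage parameters.
#' @param geneSets optional named list of gene sets (or GMT path) enabling
#'   enrichment pruning.
#' @param folds,maxDepth,eta,nrounds,minCoverage classifier parameters.
#' @return a list of class `"rssRunConfig"`.
#' @export
runConfig <- function(outDir = tempfile("rss_run_"), seed = 1L,
                      cohort = NULL, cohortConfig = NULL,
                      doPreprocess = TRUE, doConsensus = TRUE,
                      doModules = TRUE, doTrain = TRUE,
                      kRange = 2:8, nResamples = 100L, sampleFrac = 0.8,
                      linkage = "average", dropFrac = 0.5, minDelta = 0.1,
                      fdrAlpha = 0.05, beta = NULL,
                      connectivityCutoff = "median",
                      kMin = 5L, kMax = 101L, minSize = 5L,
                      moduleMethod = "sweep", stabilityFrac = 0.8,
                      geneSets = NULL,
                      folds = 5L, maxDepth = 3L, eta = 0.1, nrounds = 200L,
                      minCoverage = 0.5) {
    cfg <- as.list(environment())
    if (is.null(cfg$cohort) && is.null(cfg$cohortConfig))
        cfg$cohortConfig <- RectalSubtypes::cohortConfig(seed = as.integer(seed))
    if (is.character(cfg$cohort) && !file.exists(cfg$cohort))
        stop("cohort path does not exist: ", cfg$cohort)
    if (is.character(cfg$geneSets)) {
        if (!file.exists(cfg$geneSets))
            stop("gene-set GMT does not exist: ", cfg$geneSets)
        cfg$geneSets <- readGMT(cfg$geneSets)
    }
    class(cfg) <- "rssRunConfig"
    cfg
}

#' Read a run configuration from YAML
#'
#' Scalar pipeline parameters may be given in a YAML mapping (unknown keys
#' are rejected); cohort simulation parameters go under a `cohortConfig`
#' mapping forwarded to [cohortConfig()].
#'
#' @param path YAML file.
#' @return a run configuration as from [runConfig()].
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    ccArgs <- y$cohortConfig
    y$cohortConfig <- NULL
    known <- names(formals(runConfig))
    bad <- setdiff(names(y), known)
    if (length(bad)) stop("unknown configuration key(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(y$kRange)) y$kRange <- seq.int(y$kRange[1], y$kRange[2])
    cfg <- do.call(runConfig, y)
    if (!is.null(ccArgs))
        cfg$cohortConfig <- do.call(cohortConfig, ccArgs)
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.md5 <- function(paths) unname(tools::md5sum(paths))

#' Run the full subtype-discovery pipeline
#'
#' Executes simulate-or-load, preprocessing (quantile normalisation +
#' location-scale batch correction), consensus clustering with deltaK
#' selection, labelling at the selected k, gene-module discovery and
#' classifier training, writing every artifact plus a JSON manifest (with
#' parameters, seed and per-file md5 checksums) to `cfg$outDir`. Rerunning
#' with the same configuration and seed reproduces identical artifacts.
#' Disabled stages are marked skipped in the manifest, and stages depending
#' on them fail fast with a clear message.
#'
#' @param cfg a configuration from [runConfig()] or [readRunConfig()].
#' @return invisibly, a list with the in-memory results: `cohort`,
#'   `corrected`, `consensus`, `labels`, `modules`, `model`, `manifest`
#'   (path).
#' @export
runDiscovery <- function(cfg) {
    stopifnot(inherits(cfg, "rssRunConfig"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(created = "run", seed = cfg$seed, stages = list())
    art <- function(name) file.path(cfg$outDir, name)
    res <- list()

    ## --- cohort -----------------------------------------------------------
    res$cohort <- .stage("cohort", {
        if (is(cfg$cohort, "RectalCohort")) cfg$cohort
        else if (is.character(cfg$cohort))
            RectalCohort(readExpressionTSV(cfg$cohort))
        else {
            cc <- cfg$cohortConfig
            cc@seed <- as.integer(cfg$seed)
            generateCohort(cc)
        }
    })
    paths <- exportCohort(res$cohort, cfg$outDir, "cohort")
    manifest$stages$cohort <- list(status = "done",
                                   artifacts = as.list(paths),
                                   md5 = as.list(.md5(paths)))

    ## --- preprocess -------------------------------------------------------
    if (cfg$doPreprocess) {
        res$corrected <- .stage("preprocess", {
            x <- quantileNormalise(res$cohort)
            correctBatch(x, allowSingleBatch = TRUE)
        })
        p <- art("expression_corrected.tsv")
        writeExpressionTSV(res$corrected, p)
        manifest$stages$preprocess <- list(status = "done",
                                           artifacts = list(expression = p),
                                           md5 = as.list(.md5(p)))
    } else {
        res$corrected <- res$cohort
        manifest$stages$preprocess <- list(status = "skipped")
    }

    ## --- consensus --------------------------------------------------------
    if (cfg$doConsensus) {
        res$consensus <- .stage("consensus", consensusCluster(
            res$corrected, kRange = cfg$kRange, nResamples = cfg$nResamples,
            sampleFrac = cfg$sampleFrac, seed = cfg$seed + 1000L,
            linkage = cfg$linkage, dropFrac = cfg$dropFrac,
            minDelta = cfg$minDelta))
        res$labels <- paste0("RSS", clusterLabels(res$consensus))
        names(res$labels) <- colnames(res$corrected)

        dk <- art("deltaK.csv"); lb <- art("labels.csv"); sl <- art("silhouette.csv")
        utils::write.csv(deltaKTable(res$consensus), dk, row.names = FALSE)
        utils::write.csv(data.frame(sample_id = names(res$labels),
                                    subtype = res$labels), lb, row.names = FALSE)
        d <- spearmanDistance(res$corrected)
        sw <- silhouetteWidths(d, res$labels)
        utils::write.csv(data.frame(sample_id = names(sw$widths),
                                    subtype = res$labels,
                                    width = unname(sw$widths)),
                         sl, row.names = FALSE)
        manifest$stages$consensus <- list(
            status = "done", kSelected = kSelected(res$consensus),
            lowConfidence = res$consensus@lowConfidence,
            artifacts = list(deltaK = dk, labels = lb, silhouette = sl),
            md5 = as.list(.md5(c(dk, lb, sl))))
    } else {
        manifest$stages$consensus <- list(status = "skipped")
    }

    ## --- modules ----------------------------------------------------------
    if (cfg$doModules) {
        if (is.null(res$labels))
            stop("stage 'modules' requires subtype labels; enable the ",
                 "consensus stage first")
        res$modules <- .stage("modules", {
            sel <- selectSubtypeGenes(res$corrected, res$labels,
                                      fdrAlpha = cfg$fdrAlpha)
            net <- buildNetwork(res$corrected, beta = cfg$beta, genes = sel)
            net <- restrictByConnectivity(net, cutoff = cfg$connectivityCutoff)
            net <- tomDissimilarity(net)
            ms <- treeCutModules(net, kMin = cfg$kMin, kMax = cfg$kMax,
                                 minSize = cfg$minSize,
                                 method = cfg$moduleMethod,
                                 stabilityFrac = cfg$stabilityFrac)
            if (!is.null(cfg$geneSets))
                ms <- enrichmentPrune(ms, cfg$geneSets, alpha = cfg$fdrAlpha,
                                      minSize = cfg$minSize)
            ms
        })
        mp <- art("modules.tsv")
        writeModules(res$modules, mp)
        manifest$stages$modules <- list(
            status = "done", nModules = length(moduleList(res$modules)),
            artifacts = list(modules = mp),
            md5 = as.list(.md5(mp)))
    } else {
        manifest$stages$modules <- list(status = "skipped")
    }

    ## --- train ------------------------------------------------------------
    if (cfg$doTrain) {
        if (is.null(res$labels) || is.null(res$modules))
            stop("stage 'train' requires consensus labels and modules; ",
                 "enable the upstream stages first")
        res$model <- .stage("train", {
            sc <- moduleMedians(res$corrected, res$modules,
                                minCoverage = cfg$minCoverage)
            trainSubtypeModel(sc, res$labels, folds = cfg$folds,
                              seed = cfg$seed + 2000L,
                              maxDepth = cfg$maxDepth, eta = cfg$eta,
                              nrounds = cfg$nrounds,
                              moduleSet = res$modules,
                              minCoverage = cfg$minCoverage)
        })
        mo <- art("model.json"); cv <- art("cv_report.csv")
        saveSubtypeModel(res$model, mo)
        utils::write.csv(cvMetrics(res$model), cv, row.names = FALSE)
        manifest$stages$train <- list(
            status = "done",
            minFoldAccuracy = min(cvMetrics(res$model)$accuracy),
            artifacts = list(model = mo, cvReport = cv),
            md5 = as.list(.md5(c(mo, cv))))
    } else {
        manifest$stages$train <- list(status = "skipped")
    }

    res$manifest <- art("manifest.json")
    manifest$parameters <- cfg[setdiff(names(cfg),
                                       c("cohort", "geneSets", "cohortConfig"))]
    jsonlite::write_json(manifest, res$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(res)
}

#' Classify a cohort with a trained model, optionally with survival report
#'
#' Applies a [SubtypeModel-class] to a cohort, writes the predictions CSV
#' and, when clinical follow-up is supplied, a Kaplan-Meier table and
#' log-rank report by predicted subtype. Without clinical data the survival
#' step is skipped with a message.
#'
#' @param model a [SubtypeModel-class] or the path to a model archive.
#' @param x a [RectalCohort-class], matrix, or expression TSV path.
#' @param clinical optional data.frame with columns `sample_id`,
#'   `time_months`, `event` (and optionally `T`, `N`, `M`, `stage` — the
#'   stage imputation rule is applied when present).
#' @param outDir output directory.
#' @return invisibly, list with `predictions` (data.frame), `km` (list of
#'   per-subtype KM tables or NULL), `logrank` (list or NULL).
#' @export
runClassification <- function(model, x, clinical = NULL,
                              outDir = tempfile("rss_classify_")) {
    if (is.character(model)) model <- readSubtypeModel(model)
    if (is.character(x)) x <- RectalCohort(readExpressionTSV(x))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    pred <- .stage("classify", predictSubtypes(model, x))
    utils::write.csv(pred, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    km <- NULL; lr <- NULL
    if (is.null(clinical)) {
        message("no clinical data supplied; survival report skipped")
    } else {
        need <- c("sample_id", "time_months", "event")
        missingCols <- setdiff(need, colnames(clinical))
        if (length(missingCols))
            stop("clinical table lacks column(s): ",
                 paste(missingCols, collapse = ", "))
        cl <- merge(pred[, c("sample", "label")], clinical,
                    by.x = "sample", by.y = "sample_id")
        if (all(c("N", "M") %in% colnames(cl)) && "stage" %in% colnames(cl))
            cl$stage <- imputeStage(cl$stage, cl$N, cl$M)
        km <- lapply(split(cl, cl$label), function(g)
            kmEstimate(g$time_months, g$event))
        lr <- logrankTest(cl$time_months, cl$event, cl$label)
        kmdf <- do.call(rbind, lapply(names(km), function(g)
            data.frame(subtype = g, km[[g]])))
        utils::write.csv(kmdf, file.path(outDir, "km_table.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
            list(statistic = lr$statistic, df = lr$df, p.value = lr$p.value,
                 table = lr$table),
            file.path(outDir, "logrank.json"), auto_unbox = TRUE, digits = NA)
    }
    invisible(list(predictions = pred, km = km, logrank = lr))
}
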
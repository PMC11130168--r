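#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData "assay<-" "rowData<-"
#' @importFrom S4Vectors DataFrame metadata
NULL

## ---------------------------------------------------------------------------
## RectalCohort: a SummarizedExperiment holding log2 expression plus per-sample
## clinical/technical annotation and (for simulated data) ground truth.
## ---------------------------------------------------------------------------

#' RectalCohort: expression matrix with sample annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"exprs"` assay of log2 expression values (genes x samples). Sample
#' annotation (batch, tissue site, treatment status, TNM stage, follow-up) is
#' carried in `colData`, and for synthetic cohorts the ground truth (planted
#' subtype, gene-to-module assignment, pre/post pairing) is carried in
#' `colData`/`rowData` so that every downstream stage can be benchmarked.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("RectalCohort", contains = "SummarizedExperiment")

setValidity("RectalCohort", function(object) {
    msg <- NULL
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- assay(object, "exprs")
        if (!is.numeric(m)) msg <- c(msg, "'exprs' must be numeric")
        else if (!all(is.finite(m))) msg <- c(msg, "'exprs' must be finite")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!"batch" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'batch' column")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RectalCohort
#'
#' @param exprs numeric matrix of log2 expression, genes in rows (rownames =
#'   gene identifiers), samples in columns (colnames = sample identifiers).
#' @param batch per-sample batch label (recycled if length 1).
#' @param colData optional extra per-sample annotation (data.frame/DataFrame).
#' @param rowData optional per-gene annotation.
#' @param metadata optional list of cohort-level metadata.
#' @return a [RectalCohort-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' rc <- RectalCohort(m, batch = "b1")
#' @export
RectalCohort <- function(exprs, batch = "batch1", colData = NULL,
                         rowData = NULL, metadata = list()) {
    exprs <- as.matrix(exprs)
    if (is.null(rownames(exprs)))
        stop("'exprs' must have gene identifiers as rownames")
    if (is.null(colnames(exprs)))
        stop("'exprs' must have sample identifiers as colnames")
    cd <- DataFrame(batch = rep(as.character(batch), length.out = ncol(exprs)),
                    row.names = colnames(exprs))
    if (!is.null(colData)) {
        colData <- DataFrame(colData, row.names = colnames(exprs))
        extra <- setdiff(colnames(colData), "batch")
        cd[, extra] <- colData[, extra, drop = FALSE]
        if ("batch" %in% colnames(colData)) cd$batch <- as.character(colData$batch)
    }
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd,
                               metadata = metadata)
    if (!is.null(rowData)) rowData(se) <- DataFrame(rowData, row.names = rownames(exprs))
    new("RectalCohort", se)
}

#' @describeIn RectalCohort the log2 expression matrix (genes x samples).
#' @param x a `RectalCohort`.
#' @export
setMethod("exprsMatrix", "RectalCohort", function(x, ...) assay(x, "exprs"))

#' @describeIn RectalCohort per-sample batch labels.
#' @export
setMethod("batchLabels", "RectalCohort", function(x, ...)
    as.character(colData(x)$batch))

#' @describeIn RectalCohort planted subtype labels (NULL if not simulated).
#' @export
setMethod("trueSubtypes", "RectalCohort", function(x, ...) {
    v <- colData(x)$true_subtype
    if (is.null(v)) NULL else as.character(v)
})

#' @describeIn RectalCohort planted per-gene module labels, 0 = background.
#' @export
setMethod("trueModules", "RectalCohort", function(x, ...) {
    v <- rowData(x)$true_module
    if (is.null(v)) NULL else structure(as.integer(v), names = rownames(x))
})

#' @describeIn RectalCohort pre/post pairing keys (NA for unpaired samples).
#' @export
setMethod("pairKeys", "RectalCohort", function(x, ...) {
    v <- colData(x)$pair_key
    if (is.null(v)) NULL else structure(as.character(v), names = colnames(x))
})

setMethod("show", "RectalCohort", function(object) {
    cat("RectalCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  batches:", paste(unique(batchLabels(object)), collapse = ", "), "\n")
    ts <- trueSubtypes(object)
    if (!is.null(ts))
        cat("  planted subtypes:",
            paste(names(table(ts)), table(ts), sep = ":", collapse = ", "), "\n")
    callNextMethod()
})

## ---------------------------------------------------------------------------
## CohortConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic cohort generator
#'
#' See [cohortConfig()] for the user-facing constructor and the meaning and
#' defaults of each slot.
#'
#' @export
setClass("CohortConfig", representation(
    nSamples = "integer", nGenes = "integer", nModules = "integer",
    moduleSizes = "integer", nSubtypes = "integer",
    subtypeEffects = "matrix", stromalModules = "integer",
    withinModuleCor = "numeric", nBatches = "integer",
    batchShiftSd = "numeric", batchScaleSd = "numeric", noiseSd = "numeric",
    baselineMean = "numeric", baselineSd = "numeric",
    hazards = "numeric", censorWindow = "numeric", shiftEffect = "numeric",
    seed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- NULL
    if (length(object@moduleSizes) != object@nModules)
        msg <- c(msg, "length(moduleSizes) must equal nModules")
    if (sum(object@moduleSizes) > object@nGenes)
        msg <- c(msg, "sum(moduleSizes) must not exceed nGenes")
    if (!all(dim(object@subtypeEffects) == c(object@nModules, object@nSubtypes)))
        msg <- c(msg, "subtypeEffects must be nModules x nSubtypes")
    if (any(c(object@batchShiftSd, object@batchScaleSd, object@noiseSd,
              object@baselineSd) < 0))
        msg <- c(msg, "standard deviations must be >= 0")
    if (length(object@hazards) != object@nSubtypes || any(object@hazards <= 0))
        msg <- c(msg, "hazards must be positive, one per subtype")
    if (object@withinModuleCor <= 0 || object@withinModuleCor >= 1)
        msg <- c(msg, "withinModuleCor must lie in (0, 1)")
    if (length(object@stromalModules) &&
        any(object@stromalModules < 1 | object@stromalModules > object@nModules))
        msg <- c(msg, "stromalModules must index existing modules")
    if (object@censorWindow <= 0) msg <- c(msg, "censorWindow must be > 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nSamples, "samples,", object@nGenes, "genes,",
        object@nModules, "modules,", object@nSubtypes, "subtypes,",
        object@nBatches, "batches\n")
    cat("  max |subtype effect|:", max(abs(object@subtypeEffects)),
        " noise sd:", object@noiseSd, " seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## DuplicateReport
## ---------------------------------------------------------------------------

#' Report of duplicate samples
#'
#' Produced by [detectDuplicates()]. `groups` holds the disjoint sets of
#' sample identifiers deemed duplicates of each other, `kept` the single
#' representative retained per group.
#'
#' @export
setClass("DuplicateReport", representation(
    groups = "list", kept = "character", method = "character"))

setValidity("DuplicateReport", function(object) {
    msg <- NULL
    all_ids <- unlist(object@groups)
    if (anyDuplicated(all_ids)) msg <- c(msg, "duplicate groups must be disjoint")
    if (!all(object@kept %in% all_ids)) msg <- c(msg, "kept must lie within groups")
    if (!object@method %in% c("checksum", "correlation"))
        msg <- c(msg, "method must be 'checksum' or 'correlation'")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DuplicateReport", function(object) {
    cat("DuplicateReport (", object@method, "): ", length(object@groups),
        " duplicate group(s), ", length(unlist(object@groups)),
        " samples involved\n", sep = "")
})

## ---------------------------------------------------------------------------
## ConsensusResult
## ---------------------------------------------------------------------------

#' Result of Monti consensus clustering over a range of k
#'
#' Holds, for each candidate number of clusters k, the sample x sample
#' consensus (co-clustering fraction) matrix, the area under the consensus
#' CDF, the deltaK curve of relative area increases, the selected k, and the
#' sample labels obtained by clustering 1 - consensus at each k.
#'
#' @export
setClass("ConsensusResult", representation(
    kRange = "integer", consensus = "list", area = "numeric",
    deltaK = "numeric", kSelected = "integer", lowConfidence = "logical",
    labels = "matrix"))

setValidity("ConsensusResult", function(object) {
    msg <- NULL
    nk <- length(object@kRange)
    if (length(object@consensus) != nk || length(object@area) != nk ||
        length(object@deltaK) != nk)
        msg <- c(msg, "consensus, area and deltaK must have one entry per k")
    for (cm in object@consensus) {
        if (!isSymmetric(unname(cm)) || any(cm < 0 | cm > 1) ||
            any(abs(diag(cm) - 1) > 1e-12)) {
            msg <- c(msg, "consensus matrices must be symmetric in [0,1] with unit diagonal")
            break
        }
    }
    if (!object@kSelected %in% object@kRange)
        msg <- c(msg, "kSelected must lie in kRange")
    for (j in seq_len(ncol(object@labels)))
        if (length(unique(object@labels[, j])) != object@kRange[j])
            msg <- c(msg, sprintf("labels for k=%d do not form %d groups",
                                  object@kRange[j], object@kRange[j]))
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ConsensusResult the selected number of clusters.
#' @param x a `ConsensusResult`.
#' @export
setMethod("kSelected", "ConsensusResult", function(x, ...) x@kSelected)

#' @describeIn ConsensusResult data.frame of k, CDF area A(k) and deltaK.
#' @export
setMethod("deltaKTable", "ConsensusResult", function(x, ...)
    data.frame(k = x@kRange, area = x@area, delta = x@deltaK))

#' @describeIn ConsensusResult list of consensus matrices, one per k.
#' @export
setMethod("consensusMatrices", "ConsensusResult", function(x, ...) x@consensus)

#' @describeIn ConsensusResult sample labels; `k = NULL` uses the selected k.
#' @param k which number of clusters to return labels for.
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x, k = NULL, ...) {
    if (is.null(k)) k <- x@kSelected
    j <- match(k, x@kRange)
    if (is.na(j)) stop("k = ", k, " was not part of the consensus run")
    structure(x@labels[, j], names = rownames(x@labels))
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult over k =", paste(range(object@kRange), collapse = ".."),
        "on", nrow(object@labels), "samples\n")
    cat("  selected k:", object@kSelected,
        if (object@lowConfidence) "(low confidence)" else "", "\n")
})

## ---------------------------------------------------------------------------
## NetworkMatrices
## ---------------------------------------------------------------------------

#' Co-expression network matrices
#'
#' Spearman similarity S, unsigned power adjacency A = |S|^beta, per-gene
#' connectivity (mean adjacency to all other genes, in [0,1]) and, once
#' computed, the topological overlap dissimilarity D = 1 - TOM.
#'
#' @export
setClass("NetworkMatrices", representation(
    similarity = "matrix", adjacency = "matrix", connectivity = "numeric",
    tom = "matrix", beta = "numeric"))

setValidity("NetworkMatrices", function(object) {
    msg <- NULL
    if (!isSymmetric(unname(object@similarity)) ||
        any(abs(object@similarity) > 1 + 1e-9))
        msg <- c(msg, "similarity must be symmetric in [-1, 1]")
    if (any(object@adjacency < -1e-12 | object@adjacency > 1 + 1e-12))
        msg <- c(msg, "adjacency must lie in [0, 1]")
    if (any(object@connectivity < -1e-12 | object@connectivity > 1 + 1e-12))
        msg <- c(msg, "connectivity must lie in [0, 1]")
    if (length(object@tom) && (any(object@tom < -1e-9 | object@tom > 1 + 1e-9) ||
                               any(abs(diag(object@tom)) > 1e-12)))
        msg <- c(msg, "TOM dissimilarity must lie in [0, 1] with zero diagonal")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn NetworkMatrices Spearman similarity matrix.
#' @param x a `NetworkMatrices`.
#' @export
setMethod("similarityMatrix", "NetworkMatrices", function(x, ...) x@similarity)

#' @describeIn NetworkMatrices unsigned power adjacency matrix.
#' @export
setMethod("adjacencyMatrix", "NetworkMatrices", function(x, ...) x@adjacency)

#' @describeIn NetworkMatrices normalised per-gene connectivity.
#' @export
setMethod("connectivity", "NetworkMatrices", function(x, ...) x@connectivity)

#' @describeIn NetworkMatrices topological overlap dissimilarity (empty until
#'   [tomDissimilarity()] has been applied).
#' @export
setMethod("tomDiss", "NetworkMatrices", function(x, ...) x@tom)

#' @describeIn NetworkMatrices the soft-threshold power beta.
#' @export
setMethod("softPower", "NetworkMatrices", function(x, ...) x@beta)

setMethod("show", "NetworkMatrices", function(object) {
    cat("NetworkMatrices:", nrow(object@adjacency), "genes, beta =",
        object@beta, "\n")
    cat("  median connectivity:", signif(stats::median(object@connectivity), 3),
        " TOM computed:", length(object@tom) > 0, "\n")
})

## ---------------------------------------------------------------------------
## GeneModuleSet
## ---------------------------------------------------------------------------

#' A disjoint partition of genes into co-expression modules
#'
#' `modules` maps module identifier to gene list (ordered by decreasing
#' size); `unassigned` holds genes not placed in any module; `provenance`
#' records the parameters used to derive the partition.
#'
#' @export
setClass("GeneModuleSet", representation(
    modules = "list", unassigned = "character", provenance = "list"))

setValidity("GeneModuleSet", function(object) {
    msg <- NULL
    genes <- unlist(object@modules)
    if (anyDuplicated(genes)) msg <- c(msg, "module gene lists must be disjoint")
    if (length(intersect(genes, object@unassigned)))
        msg <- c(msg, "unassigned genes must not appear in modules")
    if (length(object@modules) && is.null(names(object@modules)))
        msg <- c(msg, "modules must be named")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GeneModuleSet named list of module gene vectors.
#' @param x a `GeneModuleSet`.
#' @export
setMethod("moduleList", "GeneModuleSet", function(x, ...) x@modules)

#' @describeIn GeneModuleSet named integer vector of module sizes.
#' @export
setMethod("moduleSizes", "GeneModuleSet", function(x, ...)
    vapply(x@modules, length, integer(1)))

#' @describeIn GeneModuleSet genes left out of all modules.
#' @export
setMethod("unassignedGenes", "GeneModuleSet", function(x, ...) x@unassigned)

#' @describeIn GeneModuleSet parameters used to build the partition.
#' @export
setMethod("provenance", "GeneModuleSet", function(x, ...) x@provenance)

setMethod("show", "GeneModuleSet", function(object) {
    sz <- moduleSizes(object)
    cat("GeneModuleSet:", length(sz), "modules,", sum(sz), "genes assigned,",
        length(object@unassigned), "unassigned\n")
    if (length(sz))
        cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
            if (length(sz) > 10) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## ModuleScoreMatrix
## ---------------------------------------------------------------------------

#' Samples x modules matrix of module-median scores
#'
#' Entry (s, m) is the median (gene-wise z-scored) expression of module m's
#' genes present in the input for sample s. `coverage` records, per module,
#' the fraction of its genes available; modules under the coverage floor are
#' NA in `scores` and FALSE in `usable`.
#'
#' @export
setClass("ModuleScoreMatrix", representation(
    scores = "matrix", coverage = "numeric", usable = "logical",
    minCoverage = "numeric"))

setValidity("ModuleScoreMatrix", function(object) {
    msg <- NULL
    if (length(object@coverage) != ncol(object@scores) ||
        length(object@usable) != ncol(object@scores))
        msg <- c(msg, "coverage/usable must have one entry per module")
    if (any(object@coverage < 0 | object@coverage > 1))
        msg <- c(msg, "coverage must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ModuleScoreMatrix the samples x modules score matrix.
#' @param x a `ModuleScoreMatrix`.
#' @export
setMethod("scoreMatrix", "ModuleScoreMatrix", function(x, ...) x@scores)

#' @describeIn ModuleScoreMatrix per-module fraction of genes available.
#' @export
setMethod("moduleCoverage", "ModuleScoreMatrix", function(x, ...) x@coverage)

setMethod("show", "ModuleScoreMatrix", function(object) {
    cat("ModuleScoreMatrix:", nrow(object@scores), "samples x",
        ncol(object@scores), "modules;", sum(object@usable),
        "module(s) at coverage >=", object@minCoverage, "\n")
})

## ---------------------------------------------------------------------------
## SubtypeModel
## ---------------------------------------------------------------------------

#' Trained multiclass subtype classifier on module-median features
#'
#' Bundles the frozen module definitions, the gradient-boosted tree ensemble
#' (stored as its portable JSON dump so serialisation round-trips exactly),
#' the class labels, per-fold cross-validation metrics, per-feature training
#' medians used to impute modules missing at prediction time, and the
#' training configuration.
#'
#' @export
setClass("SubtypeModel", representation(
    moduleSet = "GeneModuleSet", boosterRaw = "raw", classes = "character",
    cvMetrics = "data.frame", cvAUC = "matrix", featureMedians = "numeric",
    config = "list"))

setValidity("SubtypeModel", function(object) {
    msg <- NULL
    if (length(object@classes) < 2) msg <- c(msg, "need at least 2 classes")
    folds <- object@config$folds
    if (!is.null(folds) && nrow(object@cvMetrics) != folds)
        msg <- c(msg, "cvMetrics must have exactly `folds` rows")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SubtypeModel the class labels.
#' @param x a `SubtypeModel`.
#' @export
setMethod("modelClasses", "SubtypeModel", function(x, ...) x@classes)

#' @describeIn SubtypeModel per-fold accuracy (data.frame fold/accuracy).
#' @export
setMethod("cvMetrics", "SubtypeModel", function(x, ...) x@cvMetrics)

#' @describeIn SubtypeModel the frozen module definitions.
#' @export
setMethod("moduleSet", "SubtypeModel", function(x, ...) x@moduleSet)

setMethod("show", "SubtypeModel", function(object) {
    cat("SubtypeModel:", length(object@classes), "classes (",
        paste(object@classes, collapse = ", "), ") on",
        length(moduleSizes(object@moduleSet)), "modules\n")
    if (nrow(object@cvMetrics))
        cat("  CV accuracy per fold:",
            paste(sprintf("%.3f", object@cvMetrics$accuracy), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## TransitionTable
## ---------------------------------------------------------------------------

#' Pre- to post-treatment subtype transition counts
#'
#' @export
setClass("TransitionTable", representation(
    counts = "matrix", postFractions = "numeric"))

setValidity("TransitionTable", function(object) {
    msg <- NULL
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be integers")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn TransitionTable the pre x post count matrix.
#' @param x a `TransitionTable`.
#' @export
setMethod("transitionCounts", "TransitionTable", function(x, ...) x@counts)

setMethod("show", "TransitionTable", function(object) {
    cat("TransitionTable:", sum(object@counts), "pairs\n")
    print(object@counts)
})
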
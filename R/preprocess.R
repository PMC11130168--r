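## shared helpers: operations accept either a RectalCohort or a plain
## genes x samples matrix and return the same container they were given.
.getExprs <- function(x) {
    if (is(x, "RectalCohort")) exprsMatrix(x) else as.matrix(x)
}

.setExprs <- function(x, m) {
    if (is(x, "RectalCohort")) {
        SummarizedExperiment::assay(x, "exprs") <- m
        x
    } else m
}

#' Detect duplicate samples by checksum or expression correlation
#'
#' Multi-study compendia frequently contain the same sample deposited twice
#' under different identifiers. In `"checksum"` mode the raw files are
#' grouped by md5 digest, so byte-identical files form a group. In
#' `"correlation"` mode samples whose pairwise Pearson correlation reaches
#' `corThreshold` are linked and groups are the transitive closure of those
#' links. In both modes exactly one representative per group — the
#' lexicographically smallest identifier — is marked as kept.
#'
#' @param x for `"checksum"`: a character vector of file paths (names, if
#'   present, are used as sample identifiers); for `"correlation"`: a
#'   [RectalCohort-class] or genes x samples matrix.
#' @param method `"checksum"` or `"correlation"`.
#' @param corThreshold correlation at or above which two samples are deemed
#'   duplicates (default 0.999).
#' @return a [DuplicateReport-class].
#' @examples
#' m <- matrix(rnorm(300), 30, 10,
#'             dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
#' m <- cbind(m, s11 = m[, "s03"])
#' detectDuplicates(m, method = "correlation")
#' @importFrom igraph graph_from_adjacency_matrix components
#' @export
detectDuplicates <- function(x, method = c("correlation", "checksum"),
                             corThreshold = 0.999) {
    method <- match.arg(method)
    if (method == "checksum") {
        files <- x
        if (!is.character(files))
            stop("checksum mode requires a character vector of file paths")
        ids <- if (is.null(names(files))) basename(files) else names(files)
        missing <- !file.exists(files)
        if (any(missing))
            stop("cannot read file(s): ", paste(files[missing], collapse = ", "))
        sums <- tools::md5sum(files)
        if (anyNA(sums))
            stop("cannot read file(s): ",
                 paste(files[is.na(sums)], collapse = ", "))
        grp <- split(ids, sums)
    } else {
        m <- .getExprs(x)
        if (ncol(m) < 2) stop("correlation mode requires at least 2 samples")
        ids <- colnames(m)
        r <- stats::cor(m)
        adj <- (r >= corThreshold)
        diag(adj) <- FALSE
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        comp <- igraph::components(g)$membership
        grp <- split(ids, comp)
    }
    grp <- unname(grp[vapply(grp, length, integer(1)) > 1])
    grp <- lapply(grp, sort)
    grp <- grp[order(vapply(grp, `[`, character(1), 1))]
    new("DuplicateReport", groups = grp,
        kept = vapply(grp, `[`, character(1), 1), method = method)
}

#' Drop duplicate samples flagged by a DuplicateReport
#'
#' @param x a [RectalCohort-class] or matrix (columns = samples).
#' @param report a [DuplicateReport-class] from [detectDuplicates()].
#' @return `x` with the non-representative members of each duplicate group
#'   removed.
#' @export
removeDuplicates <- function(x, report) {
    stopifnot(is(report, "DuplicateReport"))
    drop <- setdiff(unlist(report@groups), report@kept)
    m <- .getExprs(x)
    keep <- setdiff(colnames(m), drop)
    if (is(x, "RectalCohort")) x[, keep] else m[, keep, drop = FALSE]
}

#' Quantile normalisation of a log2 expression matrix
#'
#' Forces every sample to share the same distribution: each column's order
#' statistics are replaced by the across-sample mean of the order statistics
#' (ties receive the average of the reference values at the tied ranks).
#' This is the standard summarised-matrix analogue of the quantile step of
#' RMA. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix with >= 2 samples.
#' @return the normalised object, same container as the input.
#' @examples
#' quantileNormalise(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
#'                   dimnames = list(paste0("g", 1:3), c("a", "b"))))
#' @importFrom limma normalizeQuantiles
#' @export
quantileNormalise <- function(x) {
    m <- .getExprs(x)
    if (ncol(m) < 2)
        stop("quantile normalisation requires at least 2 samples")
    q <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(q) <- dimnames(m)
    .setExprs(x, q)
}

#' Location-scale batch correction
#'
#' Per gene, each batch's values are centred and rescaled so that every
#' batch shares the gene's pooled (cross-batch) mean and pooled standard
#' deviation — a deterministic location-scale adjustment (ComBat without the
#' empirical-Bayes shrinkage). Genes with zero variance inside a batch are
#' centred only.
#'
#' @param x a [RectalCohort-class] (batch taken from `colData`) or matrix.
#' @param batch per-sample batch labels; required when `x` is a matrix.
#' @param allowSingleBatch if TRUE a single-batch input is returned
#'   unchanged instead of raising an error.
#' @return the corrected object, same container as the input.
#' @export
correctBatch <- function(x, batch = NULL, allowSingleBatch = FALSE) {
    m <- .getExprs(x)
    if (is.null(batch)) {
        if (!is(x, "RectalCohort"))
            stop("'batch' must be given when 'x' is a matrix")
        batch <- batchLabels(x)
    }
    batch <- as.character(batch)
    stopifnot(length(batch) == ncol(m))
    tab <- table(batch)
    if (length(tab) < 2) {
        if (allowSingleBatch) return(x)
        stop("batch correction requires >= 2 batches ",
             "(use allowSingleBatch = TRUE to pass through)")
    }
    small <- names(tab)[tab < 3]
    if (length(small))
        stop("batch(es) with fewer than 3 samples: ",
             paste(small, collapse = ", "))

    pooledMean <- rowMeans(m)
    pooledSd <- apply(m, 1, stats::sd)
    out <- m
    for (b in names(tab)) {
        idx <- which(batch == b)
        mb <- rowMeans(m[, idx, drop = FALSE])
        sb <- apply(m[, idx, drop = FALSE], 1, stats::sd)
        centred <- m[, idx, drop = FALSE] - mb
        scl <- ifelse(sb > 0, pooledSd / sb, 1)
        out[, idx] <- centred * scl + pooledMean
    }
    .setExprs(x, out)
}

#' Fraction of per-gene variance explained by batch
#'
#' One-way eta-squared of expression on batch, per gene: the between-batch
#' sum of squares over the total sum of squares. Used to quantify how much
#' batch structure remains before/after correction.
#'
#' @param x a [RectalCohort-class] or matrix.
#' @param batch per-sample batch labels (taken from the cohort if omitted).
#' @return numeric vector, one eta-squared per gene.
#' @export
batchVarianceExplained <- function(x, batch = NULL) {
    m <- .getExprs(x)
    if (is.null(batch)) batch <- batchLabels(x)
    batch <- as.factor(batch)
    gm <- rowMeans(m)
    sst <- rowSums((m - gm)^2)
    ssb <- numeric(nrow(m))
    for (b in levels(batch)) {
        idx <- which(batch == b)
        mb <- rowMeans(m[, idx, drop = FALSE])
        ssb <- ssb + length(idx) * (mb - gm)^2
    }
    ifelse(sst > 0, ssb / sst, 0)
}

#' Merge expression studies on their common genes
#'
#' Restricts every study to the intersection of gene identifiers,
#' concatenates samples and labels each sample's batch with its source
#' study. Sample identifiers must be unique across studies (deduplicate or
#' rename first).
#'
#' @param studies a named list of [RectalCohort-class] objects and/or
#'   genes x samples matrices; names become batch labels (defaults
#'   `study1`, `study2`, ...).
#' @param minGenes minimum size of the gene intersection (default 100);
#'   a smaller overlap raises an error.
#' @return a [RectalCohort-class] with `batch` = source study.
#' @export
mergeStudies <- function(studies, minGenes = 100L) {
    if (!is.list(studies) || length(studies) < 2)
        stop("'studies' must be a list of at least 2 matrices/cohorts")
    if (is.null(names(studies)) || any(names(studies) == ""))
        names(studies) <- paste0("study", seq_along(studies))
    mats <- lapply(studies, .getExprs)
    common <- Reduce(intersect, lapply(mats, rownames))
    if (length(common) < minGenes)
        stop("gene intersection across studies has only ", length(common),
             " genes (minimum ", minGenes, ")")
    allIds <- unlist(lapply(mats, colnames))
    if (anyDuplicated(allIds))
        stop("duplicate sample identifiers across studies: ",
             paste(unique(allIds[duplicated(allIds)]), collapse = ", "),
             " (deduplicate or rename before merging)")
    merged <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
    batch <- rep(names(studies), vapply(mats, ncol, integer(1)))
    RectalCohort(merged, batch = batch)
}
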
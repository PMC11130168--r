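#' Spearman correlation distance between samples
#'
#' `1 - Spearman correlation` between sample expression profiles (computed
#' across genes) — the distance used throughout subtype discovery, chosen to
#' be consistent with the Spearman-based co-expression network stage and
#' robust to monotone platform differences.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @return a symmetric samples x samples distance matrix with zero diagonal.
#' @export
spearmanDistance <- function(x) {
    m <- .getExprs(x)
    d <- 1 - stats::cor(m, method = "spearman")
    diag(d) <- 0
    d
}

.checkDist <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-8))
        stop("distance matrix must have zero diagonal")
    d
}

.linkageMethod <- function(linkage) {
    switch(linkage, average = "average", complete = "complete",
           ward = "ward.D2", stop("unknown linkage: ", linkage))
}

#' Cut an agglomerative clustering at k clusters
#'
#' Average / complete / Ward agglomerative clustering of a distance matrix,
#' cut into `k` groups. Ties in merge heights are resolved by the
#' deterministic pair ordering of [stats::hclust].
#'
#' @param dist symmetric distance matrix with zero diagonal (or a `dist`).
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (Ward.D2).
#' @param k number of clusters, `2 <= k <= n`.
#' @return integer labels named by sample.
#' @export
hierarchicalLabels <- function(dist, linkage = "average", k) {
    d <- .checkDist(dist)
    n <- nrow(d)
    if (k < 2 || k > n) stop("k must lie in [2, ", n, "]")
    hc <- stats::hclust(stats::as.dist(d), method = .linkageMethod(linkage))
    stats::cutree(hc, k = k)
}

#' Monti consensus matrix at a single k
#'
#' Repeatedly subsamples a fraction of the samples, clusters each subsample
#' hierarchically on the Spearman correlation distance cut at `k`, and
#' records for every sample pair the fraction of subsamples in which the two
#' co-clustered among those in which both were drawn. Pairs never drawn
#' together get consensus 0 and are flagged in the `"neverSampled"`
#' attribute. The result is deterministic for a fixed seed.
#'
#' @param x a [RectalCohort-class], genes x samples matrix, or a precomputed
#'   symmetric sample distance matrix (`isDistance = TRUE`).
#' @param k number of clusters per subsample.
#' @param nResamples number of subsamples (>= 2; default 100).
#' @param sampleFrac fraction of samples drawn per subsample (default 0.8).
#' @param seed RNG seed.
#' @param linkage linkage passed to [hierarchicalLabels()].
#' @param isDistance set TRUE when `x` already is a distance matrix.
#' @return symmetric samples x samples consensus matrix in `[0, 1]` with unit
#'   diagonal; attribute `"neverSampled"` marks pairs with no co-draw.
#' @export
consensusMatrix <- function(x, k, nResamples = 100L, sampleFrac = 0.8,
                            seed = 1L, linkage = "average",
                            isDistance = FALSE) {
    if (nResamples < 2) stop("nResamples must be >= 2")
    if (sampleFrac <= 0 || sampleFrac > 1)
        stop("sampleFrac must lie in (0, 1]")
    d <- if (isDistance) .checkDist(x) else spearmanDistance(x)
    n <- nrow(d)
    nSub <- max(2L, floor(sampleFrac * n))
    if (k > nSub)
        stop("k = ", k, " exceeds the subsample size ", nSub)
    ids <- rownames(d)
    if (is.null(ids)) ids <- colnames(d)

    set.seed(seed)
    hits <- matrix(0, n, n)   # co-cluster counts
    draws <- matrix(0, n, n)  # co-draw counts
    method <- .linkageMethod(linkage)
    for (r in seq_len(nResamples)) {
        idx <- if (nSub == n) seq_len(n) else sort(sample.int(n, nSub))
        lab <- stats::cutree(
            stats::hclust(stats::as.dist(d[idx, idx]), method = method), k = k)
        ind <- outer(lab, lab, "==")
        hits[idx, idx] <- hits[idx, idx] + ind
        draws[idx, idx] <- draws[idx, idx] + 1
    }
    cons <- ifelse(draws > 0, hits / pmax(draws, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    never <- draws == 0
    diag(never) <- FALSE
    attr(cons, "neverSampled") <- never
    cons
}

## area under the empirical CDF of the upper-triangle consensus values,
## trapezoid rule over the sorted values anchored at 0 and 1.
.consensusArea <- function(cons) {
    v <- sort(cons[upper.tri(cons)])
    xs <- c(0, v, 1)
    Fv <- c(0, seq_along(v) / length(v), 1)
    ## ecdf at each knot (right-continuous)
    Fknot <- vapply(xs, function(z) mean(v <= z), numeric(1))
    sum(diff(xs) * (utils::head(Fknot, -1) + utils::tail(Fknot, -1)) / 2)
}

#' deltaK model selection over a range of consensus matrices
#'
#' Computes, for each candidate k, the area A(k) under the empirical CDF of
#' the consensus values and the relative area increase
#' `delta(2) = A(2)`, `delta(k) = (A(k) - A(k-1)) / A(k-1)`. The visual
#' "elbow" of the deltaK curve is operationalised as the smallest k >= 3
#' with an appreciable delta (`delta(k) >= minDelta`) that collapses at the
#' next k (`delta(k+1) < dropFrac * delta(k)`); if no such drop exists the
#' argmax of delta is returned (which degenerates to k = 2 for structureless
#' data, since delta(2) = A(2)). When no delta at k >= 3 reaches `minDelta`
#' the selection is flagged low-confidence. Final labels per k come from
#' average-linkage clustering of `1 - consensus`.
#'
#' @param consensus list of consensus matrices, one per k (as produced by
#'   [consensusMatrix()]).
#' @param kRange the corresponding numbers of clusters; must be contiguous,
#'   start at 2 and contain at least 3 values.
#' @param dropFrac collapse factor defining the elbow (default 0.5).
#' @param minDelta smallest delta regarded as an appreciable increase
#'   (default 0.1); also the low-confidence threshold.
#' @return a [ConsensusResult-class].
#' @export
deltaKSelect <- function(consensus, kRange, dropFrac = 0.5, minDelta = 0.1) {
    kRange <- as.integer(kRange)
    if (length(kRange) < 3) stop("need at least 3 candidate k")
    if (kRange[1] != 2L || any(diff(kRange) != 1L))
        stop("kRange must be contiguous starting at 2")
    if (length(consensus) != length(kRange))
        stop("one consensus matrix per k is required")

    area <- vapply(consensus, .consensusArea, numeric(1))
    delta <- numeric(length(kRange))
    delta[1] <- area[1]
    for (j in seq_along(kRange)[-1])
        delta[j] <- if (area[j - 1] > 0) (area[j] - area[j - 1]) / area[j - 1] else 0

    kSel <- NA_integer_
    for (j in seq_along(kRange)) {
        k <- kRange[j]
        if (k < 3 || j == length(kRange)) next
        if (delta[j] >= minDelta && delta[j + 1] < dropFrac * delta[j]) {
            kSel <- k
            break
        }
    }
    if (is.na(kSel)) kSel <- kRange[which.max(delta)]
    lowConf <- max(c(delta[kRange >= 3], 0)) < minDelta

    n <- nrow(consensus[[1]])
    labels <- matrix(NA_integer_, n, length(kRange),
                     dimnames = list(rownames(consensus[[1]]),
                                     paste0("k", kRange)))
    for (j in seq_along(kRange)) {
        d <- 1 - consensus[[j]]
        diag(d) <- 0
        labels[, j] <- stats::cutree(
            stats::hclust(stats::as.dist(d), method = "average"), k = kRange[j])
    }
    new("ConsensusResult", kRange = kRange, consensus = consensus,
        area = unname(area), deltaK = unname(delta),
        kSelected = as.integer(kSel), lowConfidence = lowConf,
        labels = labels)
}

#' Consensus clustering with deltaK selection of k
#'
#' Runs [consensusMatrix()] for every k in `kRange` on the Spearman
#' correlation distance between samples and selects the number of clusters
#' with [deltaKSelect()]. The per-k resampling streams are derived
#' deterministically from `seed`.
#'
#' @inheritParams consensusMatrix
#' @inheritParams deltaKSelect
#' @param kRange contiguous candidate cluster numbers starting at 2
#'   (default `2:8`).
#' @return a [ConsensusResult-class].
#' @examples
#' rc <- generateCohort(cohortConfig(nSamples = 45, nGenes = 300,
#'                                   moduleSizes = c(40, 30, 30),
#'                                   effect = 2, seed = 7))
#' cc <- consensusCluster(rc, kRange = 2:5, nResamples = 20)
#' kSelected(cc)
#' @export
consensusCluster <- function(x, kRange = 2:8, nResamples = 100L,
                             sampleFrac = 0.8, seed = 1L, linkage = "average",
                             dropFrac = 0.5, minDelta = 0.1,
                             isDistance = FALSE) {
    d <- if (isDistance) .checkDist(x) else spearmanDistance(x)
    consensus <- lapply(seq_along(kRange), function(j)
        consensusMatrix(d, k = kRange[j], nResamples = nResamples,
                        sampleFrac = sampleFrac, seed = seed + j - 1L,
                        linkage = linkage, isDistance = TRUE))
    deltaKSelect(consensus, kRange, dropFrac = dropFrac, minDelta = minDelta)
}

#' Silhouette widths for a clustering
#'
#' For sample i with mean intra-cluster distance a(i) and smallest mean
#' distance to another cluster b(i), the width is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; members of singleton clusters
#' get width 0.
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param labels cluster labels, one per sample; at least 2 clusters.
#' @return list with `widths` (per sample), `clusterMeans` (per cluster) and
#'   `meanWidth`.
#' @export
silhouetteWidths <- function(dist, labels) {
    d <- .checkDist(dist)
    n <- nrow(d)
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
    cls <- sort(unique(labels))
    if (length(cls) < 2) stop("silhouette requires at least 2 clusters")

    sizes <- table(labels)[cls]
    ind <- vapply(cls, function(cl) labels == cl, logical(n))
    sums <- d %*% ind                      # n x k: total distance to cluster
    widths <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels[i]
        nOwn <- sizes[[own]]
        if (nOwn == 1) { widths[i] <- 0; next }
        a <- sums[i, own] / (nOwn - 1)
        others <- setdiff(cls, own)
        b <- min(sums[i, others] / sizes[others])
        widths[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    names(widths) <- rownames(d)
    clusterMeans <- vapply(cls, function(cl) mean(widths[labels == cl]),
                           numeric(1))
    list(widths = widths, clusterMeans = clusterMeans,
         meanWidth = mean(widths))
}

#' Principal-component diagnostic of a clustering
#'
#' Thin wrapper over [stats::prcomp] returning per-sample scores on the
#' leading components together with cluster labels — the standard visual
#' check that discovered subtypes occupy distinct regions of expression
#' space.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @param labels optional cluster labels to attach.
#' @param nComponents number of components to keep (default 2).
#' @return data.frame of sample, PC scores and (optionally) cluster.
#' @export
pcaDiagnostics <- function(x, labels = NULL, nComponents = 2L) {
    m <- .getExprs(x)
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(min(nComponents, ncol(pc$x))), drop = FALSE]
    out <- data.frame(sample = colnames(m), sc, check.names = FALSE)
    if (!is.null(labels)) out$cluster <- labels
    out
}
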
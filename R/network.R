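#' Per-gene two-group differential expression
#'
#' One-way ANOVA F-test per gene between two sample groups — for two groups
#' identical to the two-sided pooled-variance t-test — with
#' Benjamini-Hochberg adjustment across all tested genes. The fold change is
#' the difference of group means, which on log2 data is the log2 fold
#' change. Genes constant across all samples get p = 1 by convention and are
#' flagged.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @param groups two-level factor (or coercible), one entry per sample; both
#'   groups need >= 2 samples.
#' @param fdrAlpha significance level on the adjusted q (recorded in the
#'   `significant` column; default 0.05).
#' @return data.frame with columns `gene`, `statistic` (F), `p`, `q`,
#'   `lfc` (mean of the second level minus mean of the first), `constant`,
#'   `significant`.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' m[1, 6:10] <- m[1, 6:10] + 3
#' head(twoGroupDiff(m, rep(c("a", "b"), each = 5)))
#' @export
twoGroupDiff <- function(x, groups, fdrAlpha = 0.05) {
    m <- .getExprs(x)
    groups <- factor(groups)
    if (nlevels(groups) != 2)
        stop("exactly two groups are required")
    n1 <- sum(groups == levels(groups)[1])
    n2 <- sum(groups == levels(groups)[2])
    if (min(n1, n2) < 2) stop("both groups need at least 2 samples")

    m1 <- rowMeans(m[, groups == levels(groups)[1], drop = FALSE])
    m2 <- rowMeans(m[, groups == levels(groups)[2], drop = FALSE])
    v1 <- apply(m[, groups == levels(groups)[1], drop = FALSE], 1, stats::var)
    v2 <- apply(m[, groups == levels(groups)[2], drop = FALSE], 1, stats::var)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)

    Fstat <- ifelse(se2 > 0, (m2 - m1)^2 / se2,
                    ifelse(m1 == m2, 0, Inf))
    p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
    p[is.infinite(Fstat)] <- 0
    constant <- apply(m, 1, function(r) max(r) == min(r))
    p[constant] <- 1
    Fstat[constant] <- 0
    q <- stats::p.adjust(p, method = "BH")
    data.frame(gene = rownames(m), statistic = Fstat, p = p, q = q,
               lfc = m2 - m1, constant = constant,
               significant = q < fdrAlpha, row.names = NULL)
}

#' Select genes separating any pair of subtypes
#'
#' Runs [twoGroupDiff()] on every pair of subtype labels and returns the
#' union of genes significant (adjusted q < `fdrAlpha`) in at least one
#' pairwise comparison. By default the BH adjustment is applied jointly over
#' the p-values of all pairwise comparisons, so the false-discovery rate of
#' the returned union is controlled at `fdrAlpha`; `adjust =
#' "per.comparison"` instead adjusts each comparison on its own before
#' taking the union.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @param labels subtype label per sample; every subtype needs >= 2 samples.
#' @param fdrAlpha FDR level (default 0.05).
#' @param adjust `"pooled"` (default) or `"per.comparison"`.
#' @return sorted character vector of selected genes; attribute
#'   `"pairwise"` holds the per-comparison result tables.
#' @export
selectSubtypeGenes <- function(x, labels, fdrAlpha = 0.05,
                               adjust = c("pooled", "per.comparison")) {
    adjust <- match.arg(adjust)
    m <- .getExprs(x)
    labels <- as.character(labels)
    stopifnot(length(labels) == ncol(m))
    tab <- table(labels)
    if (length(tab) < 2) stop("at least two subtypes are required")
    if (any(tab < 2))
        stop("subtype(s) with fewer than 2 samples: ",
             paste(names(tab)[tab < 2], collapse = ", "))

    pairs <- utils::combn(sort(names(tab)), 2, simplify = FALSE)
    res <- lapply(pairs, function(pr) {
        idx <- labels %in% pr
        twoGroupDiff(m[, idx, drop = FALSE], factor(labels[idx], levels = pr),
                     fdrAlpha = fdrAlpha)
    })
    names(res) <- vapply(pairs, paste, character(1), collapse = "_vs_")

    if (adjust == "pooled") {
        allP <- unlist(lapply(res, `[[`, "p"))
        allQ <- stats::p.adjust(allP, method = "BH")
        qs <- split(allQ, rep(seq_along(res), each = nrow(res[[1]])))
        for (j in seq_along(res)) {
            res[[j]]$q <- qs[[j]]
            res[[j]]$significant <- res[[j]]$q < fdrAlpha
        }
    }
    sel <- sort(unique(unlist(lapply(res, function(r) r$gene[r$significant]))))
    attr(sel, "pairwise") <- res
    sel
}

## Otsu threshold on a numeric vector: the split point maximising the
## between-class variance of the two resulting groups. Deterministic.
.otsuThreshold <- function(v) {
    v <- sort(v)
    n <- length(v)
    best <- -Inf; thr <- v[1]
    csum <- cumsum(v)
    tot <- csum[n]
    for (i in seq_len(n - 1)) {
        if (v[i] == v[i + 1]) next
        m1 <- csum[i] / i
        m2 <- (tot - csum[i]) / (n - i)
        bc <- i * (n - i) * (m1 - m2)^2
        if (bc > best) { best <- bc; thr <- (v[i] + v[i + 1]) / 2 }
    }
    thr
}

.scaleFreeR2 <- function(k, nBins = 10L) {
    k <- k[k > 0]
    if (length(unique(k)) < 3) return(0)
    cuts <- cut(k, breaks = nBins)
    p <- tapply(k, cuts, length)
    km <- tapply(k, cuts, mean)
    keep <- !is.na(p) & p > 0
    if (sum(keep) < 3) return(0)
    fit <- stats::lm(log10(p[keep]) ~ log10(km[keep]))
    if (stats::coef(fit)[2] >= 0) return(0)
    summary(fit)$r.squared
}

#' Build an unsigned power-adjacency co-expression network
#'
#' Computes the gene x gene Spearman similarity S over samples, the unsigned
#' power adjacency `A = |S|^beta`, and the normalised connectivity
#' `k_i = sum_{j != i} a_ij / (n - 1)` (so `k_i` lies in `[0, 1]`). If
#' `beta` is not given, the smallest beta in 1..10 whose connectivity
#' distribution fits a scale-free law with R^2 >= 0.8 is chosen; if none
#' does, beta = 6.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix (>= 2 genes,
#'   >= 4 samples), typically already restricted to subtype-separating genes.
#' @param beta soft-threshold power; NULL (default) triggers scale-free
#'   selection.
#' @param genes optional subset of gene identifiers to use.
#' @return a [NetworkMatrices-class] (TOM slot empty until
#'   [tomDissimilarity()]).
#' @export
buildNetwork <- function(x, beta = NULL, genes = NULL) {
    m <- .getExprs(x)
    if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
    if (nrow(m) < 2) stop("at least 2 genes are required")
    if (ncol(m) < 4) stop("at least 4 samples are required")
    noVar <- apply(m, 1, function(r) max(r) == min(r))
    if (any(noVar)) {
        warning("dropping ", sum(noVar), " zero-variance gene(s)")
        m <- m[!noVar, , drop = FALSE]
        if (nrow(m) < 2) stop("fewer than 2 genes left after dropping")
    }
    S <- stats::cor(t(m), method = "spearman")
    n <- nrow(S)

    adjFor <- function(b) {
        A <- abs(S)^b
        diag(A) <- 1
        A
    }
    connFor <- function(A) (rowSums(A) - 1) / (n - 1)

    if (is.null(beta)) {
        beta <- 6
        for (b in 1:10) {
            if (.scaleFreeR2(connFor(adjFor(b))) >= 0.8) { beta <- b; break }
        }
    }
    A <- adjFor(beta)
    new("NetworkMatrices", similarity = S, adjacency = A,
        connectivity = connFor(A), tom = matrix(numeric(0), 0, 0),
        beta = as.numeric(beta))
}

#' Restrict a network to high-connectivity genes
#'
#' Keeps genes whose connectivity is strictly greater than the cutoff and
#' re-slices the similarity and adjacency matrices. Connectivity values are
#' carried over, not recomputed, so the reported connectivities remain on
#' the scale of the full network.
#'
#' Three cutoffs are available: `"median"` (the median connectivity across
#' genes — keeps the hub half of the network), an explicit numeric value,
#' or `"bimodal"` — an Otsu threshold on log10 connectivity that exploits
#' the strongly bimodal connectivity distribution arising when genuinely
#' co-expressed genes mix with background genes that slipped through the
#' differential filter; it removes the background mode without sacrificing
#' small modules, whose genes have lower connectivity than large-module
#' hubs and are therefore lost under the median rule.
#'
#' @param net a [NetworkMatrices-class].
#' @param cutoff `"median"`, `"bimodal"`, or an explicit numeric
#'   connectivity value.
#' @return the restricted [NetworkMatrices-class].
#' @export
restrictByConnectivity <- function(net, cutoff = "median") {
    stopifnot(is(net, "NetworkMatrices"))
    k <- connectivity(net)
    if (length(k) < 4) stop("at least 4 genes are required")
    cut <- if (identical(cutoff, "median")) stats::median(k)
           else if (identical(cutoff, "bimodal"))
               10^.otsuThreshold(log10(pmax(k, 1e-12)))
           else as.numeric(cutoff)
    keep <- which(k > cut)
    if (length(keep) < 2)
        stop("fewer than 2 genes above the connectivity cutoff ",
             signif(cut, 4))
    new("NetworkMatrices",
        similarity = net@similarity[keep, keep],
        adjacency = net@adjacency[keep, keep],
        connectivity = k[keep],
        tom = matrix(numeric(0), 0, 0), beta = net@beta)
}

#' Topological overlap dissimilarity
#'
#' For adjacency a in `[0, 1]` (diagonal ignored) computes
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(K_i, K_j) + 1 - a_{ij}}}
#' with `K_i` the unnormalised adjacency row sum (excluding the diagonal),
#' `TOM_ii = 1`, and returns the network with `D = 1 - TOM` filled in. Two
#' genes are topologically similar when they are directly connected and
#' share neighbours.
#'
#' @param net a [NetworkMatrices-class] (or a plain adjacency matrix).
#' @return the [NetworkMatrices-class] with the `tom` slot set to D.
#' @export
tomDissimilarity <- function(net) {
    A <- if (is(net, "NetworkMatrices")) net@adjacency else as.matrix(net)
    if (!isSymmetric(unname(A)) || any(A < -1e-12 | A > 1 + 1e-12))
        stop("adjacency must be symmetric in [0, 1]")
    diag(A) <- 0
    K <- rowSums(A)
    L <- A %*% A                      # shared-neighbour sums (diag(A)=0
                                      # removes u = i and u = j terms)
    denom <- outer(K, K, pmin) + 1 - A
    stopifnot(all(denom > 0))
    tom <- (L + A) / denom
    diag(tom) <- 1
    D <- 1 - tom
    D[D < 0] <- 0
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- dimnames(A)
    if (is(net, "NetworkMatrices")) {
        net@tom <- D
        validObject(net)
        net
    } else {
        new("NetworkMatrices", similarity = A, adjacency = A,
            connectivity = K / max(1, nrow(A) - 1), tom = D, beta = 1)
    }
}
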
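## Independent brute-force oracles used to pin down the numerical operations.
## Each is written from the defining formula, independently of the package
## implementation paths it checks.

## Benjamini-Hochberg step-up, straight from the definition
bfBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## silhouette widths by a direct double loop
bfSilhouette <- function(d, labels) {
    n <- nrow(d)
    out <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels[i]
        sameIdx <- setdiff(which(labels == own), i)
        if (!length(sameIdx)) { out[i] <- 0; next }
        a <- mean(d[i, sameIdx])
        b <- Inf
        for (cl in setdiff(unique(labels), own))
            b <- min(b, mean(d[i, labels == cl]))
        out[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    out
}

## TOM dissimilarity by a triple loop
bfTOM <- function(A) {
    diag(A) <- 0
    n <- nrow(A)
    K <- rowSums(A)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
        D[i, j] <- 1 - (l + A[i, j]) / (min(K[i], K[j]) + 1 - A[i, j])
    }
    D
}

## Kaplan-Meier by explicit per-time recomputation
bfKM <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- numeric(length(ts))
    cur <- 1
    for (j in seq_along(ts)) {
        n <- sum(time >= ts[j])
        d <- sum(time == ts[j] & event == 1)
        cur <- cur * (1 - d / n)
        s[j] <- cur
    }
    data.frame(time = ts, survival = s)
}

## two-group log-rank statistic with the O/E/V sums done longhand
bfLogrank2 <- function(time, event, group) {
    gs <- sort(unique(group))
    stopifnot(length(gs) == 2)
    O <- 0; E <- 0; V <- 0
    for (t0 in sort(unique(time[event == 1]))) {
        n <- sum(time >= t0)
        n1 <- sum(time >= t0 & group == gs[1])
        d <- sum(time == t0 & event == 1)
        d1 <- sum(time == t0 & event == 1 & group == gs[1])
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

## average-linkage agglomeration by scanning all cluster pairs at each step
bfAverageLinkageLabels <- function(d, k) {
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    while (length(clusters) > k) {
        best <- c(NA, NA); bestH <- Inf
        for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
            h <- mean(d[clusters[[i]], clusters[[j]]])
            if (h < bestH) { bestH <- h; best <- c(i, j) }
        }
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    lab
}

## hypergeometric upper tail by direct summation
bfHyperTail <- function(overlap, setSize, universe, moduleSize) {
    sum(vapply(overlap:min(setSize, moduleSize), function(j)
        choose(setSize, j) * choose(universe - setSize, moduleSize - j) /
            choose(universe, moduleSize), numeric(1)))
}

## small synthetic cohort for fast tests
smallConfig <- function(seed = 1L, effect = 1.0, ...) {
    cohortConfig(nSamples = 45L, nGenes = 300L,
                 moduleSizes = c(40L, 30L, 20L), nBatches = 2L,
                 effect = effect, seed = seed, ...)
}

## partition both ways into a named label vector keyed by gene
moduleLabelsOf <- function(ms) {
    mods <- moduleList(ms)
    structure(rep(names(mods), lengths(mods)), names = unlist(mods))
}

jaccardBestMatch <- function(ms, truth, module) {
    planted <- names(truth)[truth == module]
    max(vapply(moduleList(ms), function(g)
        length(intersect(g, planted)) / length(union(g, planted)), numeric(1)))
}
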
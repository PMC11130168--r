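## well-separated Gaussian blobs in sample space, as a distance matrix
blobDistance <- function(nPer = 10L, k = 3L, sep = 8, seed = 1L) {
    set.seed(seed)
    centers <- matrix(rnorm(k * 5, sd = sep), k, 5)
    x <- centers[rep(seq_len(k), each = nPer), ] +
        matrix(rnorm(k * nPer * 5), k * nPer, 5)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(sprintf("s%02d", seq_len(k * nPer)),
                        sprintf("s%02d", seq_len(k * nPer)))
    list(d = d, truth = rep(seq_len(k), each = nPer))
}

test_that("hierarchical labels recover separable pairs and validate input", {
    d <- matrix(c(0, 1, 9, 9,
                  1, 0, 9, 9,
                  9, 9, 0, 1,
                  9, 9, 1, 0), 4, 4)
    lab <- hierarchicalLabels(d, k = 2)
    expect_equal(lab[1], lab[2])
    expect_equal(lab[3], lab[4])
    expect_false(lab[1] == lab[3])

    expect_equal(length(unique(hierarchicalLabels(d, k = 4))), 4L)
    expect_error(hierarchicalLabels(matrix(1:16, 4, 4), k = 2), "symmetric")
    expect_error(hierarchicalLabels(d, k = 5), "k must lie")
})

test_that("average-linkage labels agree with a brute-force agglomerator", {
    set.seed(7)
    for (rep in 1:3) {
        x <- matrix(rnorm(8 * 3), 8, 3)
        d <- as.matrix(dist(x))
        lab <- hierarchicalLabels(d, linkage = "average", k = 3)
        bf <- bfAverageLinkageLabels(d, k = 3)
        ## same partition up to relabelling
        expect_equal(length(unique(paste(lab, bf))), 3L)
    }
})

test_that("consensus matrices obey their contract", {
    b <- blobDistance(nPer = 8, seed = 2)
    ## duplicate samples always co-cluster: consensus entry 1
    d2 <- b$d
    d2[1, 2] <- d2[2, 1] <- 0   # make samples 1 and 2 effectively identical
    cm <- consensusMatrix(d2, k = 3, nResamples = 30, seed = 1,
                          isDistance = TRUE)
    expect_equal(cm[1, 2], 1)
    expect_true(isSymmetric(unname(cm)))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(unname(diag(cm)), rep(1, nrow(cm)))

    ## no resampling variance at sampleFrac = 1: entries are 0 or 1
    cmFull <- consensusMatrix(b$d, k = 3, nResamples = 5, sampleFrac = 1,
                              seed = 1, isDistance = TRUE)
    expect_true(all(cmFull %in% c(0, 1)))
    ## and the full-draw consensus is invariant to sample permutation
    p <- sample(nrow(b$d))
    cmPerm <- consensusMatrix(b$d[p, p], k = 3, nResamples = 5,
                              sampleFrac = 1, seed = 1, isDistance = TRUE)
    attr(cmPerm, "neverSampled") <- NULL
    expect_equal(unname(cmPerm), unname(cmFull[p, p]),
                 ignore_attr = TRUE)

    ## planted blobs: near-perfect within, near-zero between
    cc <- consensusMatrix(b$d, k = 3, nResamples = 50, sampleFrac = 0.8,
                          seed = 3, isDistance = TRUE)
    same <- outer(b$truth, b$truth, "==")
    ut <- upper.tri(cc)
    expect_gt(mean(cc[same & ut]), 0.95)
    expect_lt(mean(cc[!same & ut]), 0.05)

    expect_error(consensusMatrix(b$d, k = 30, isDistance = TRUE), "subsample")
    expect_error(consensusMatrix(b$d, k = 3, nResamples = 1,
                                 isDistance = TRUE), "nResamples")
})

test_that("deltaK selects the planted number of clusters", {
    hits <- vapply(1:5, function(s) {
        b <- blobDistance(nPer = 15, k = 3, seed = s)
        cc <- consensusCluster(b$d, kRange = 2:8, nResamples = 40,
                               seed = s, isDistance = TRUE)
        kSelected(cc)
    }, numeric(1))
    expect_gte(sum(hits == 3), 4)
})

test_that("deltaK handles degenerate and structureless input", {
    ## structureless data: the procedure still completes and returns a k
    set.seed(9)
    x <- matrix(rnorm(40 * 20), 20, 40)
    d <- as.matrix(dist(t(x)) / max(dist(t(x))))
    dimnames(d) <- list(paste0("s", 1:40), paste0("s", 1:40))
    cc <- consensusCluster(d, kRange = 2:6, nResamples = 30, seed = 1,
                           isDistance = TRUE)
    expect_true(kSelected(cc) %in% 2:6)

    ## when no delta at k >= 3 is appreciable the result is flagged
    ## low-confidence and the argmax fallback lands on k = 2
    n <- 16
    mkCons <- function(frac) {
        ## block structure diluted so consensus values shrink slightly with k
        cm <- matrix(frac, n, n); diag(cm) <- 1
        dimnames(cm) <- list(paste0("s", 1:n), paste0("s", 1:n))
        cm
    }
    consSmall <- lapply(c(0.50, 0.49, 0.485, 0.482), mkCons)
    resSmall <- deltaKSelect(consSmall, 2:5)
    expect_true(resSmall@lowConfidence)
    expect_equal(kSelected(resSmall), 2L)

    ## constant areas: delta(k > 2) = 0, selection falls back to k = 2
    n <- 12
    cons <- lapply(2:5, function(k) {
        cm <- matrix(0.5, n, n); diag(cm) <- 1
        dimnames(cm) <- list(paste0("s", 1:n), paste0("s", 1:n))
        cm
    })
    res <- deltaKSelect(cons, 2:5)
    expect_equal(res@deltaK[-1], rep(0, 3))
    expect_equal(kSelected(res), 2L)

    expect_error(deltaKSelect(cons[1:2], 2:3), "at least 3")
    expect_error(deltaKSelect(cons, 3:6), "starting at 2")
})

test_that("silhouette widths match the definition and its oracles", {
    ## two tight, far-apart clusters: widths tend to 1
    d <- matrix(1, 4, 4); d[1, 2] <- d[2, 1] <- 0.001
    d[3, 4] <- d[4, 3] <- 0.001; diag(d) <- 0
    sw <- silhouetteWidths(d, c(1, 1, 2, 2))
    expect_true(all(sw$widths > 0.99))

    ## toy instance equals the brute-force double loop exactly
    set.seed(10)
    x <- matrix(rnorm(6 * 2), 6, 2)
    dt <- as.matrix(dist(x))
    lab <- c(1, 1, 2, 2, 3, 3)
    expect_equal(unname(silhouetteWidths(dt, lab)$widths),
                 bfSilhouette(dt, lab), tolerance = 1e-12)

    ## and agrees with the reference implementation in cluster
    skip_if_not_installed("cluster")
    set.seed(11)
    x2 <- matrix(rnorm(20 * 3), 20, 3)
    d2 <- as.matrix(dist(x2))
    lab2 <- sample(1:3, 20, replace = TRUE)
    ref <- cluster::silhouette(lab2, dist(x2))
    expect_equal(unname(silhouetteWidths(d2, lab2)$widths)[order(lab2)],
                 ref[, "sil_width"][order(lab2)], tolerance = 1e-12)

    ## random labels on structureless data have mean width near 0
    set.seed(12)
    d3 <- as.matrix(dist(matrix(rnorm(100 * 5), 100, 5)))
    expect_lt(abs(silhouetteWidths(d3, sample(1:3, 100, TRUE))$meanWidth), 0.1)

    expect_error(silhouetteWidths(d, rep(1, 4)), "2 clusters")
})
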
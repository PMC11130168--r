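test_that("two-group differential testing matches its definitions", {
    set.seed(20)
    groups <- rep(c("a", "b"), each = 10)
    m <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
    m[1, groups == "b"] <- m[1, groups == "b"] + 5
    res <- twoGroupDiff(m, groups)

    ## F equals the square of the pooled t and p matches t.test(var.equal)
    for (g in c(1, 7, 23)) {
        tt <- t.test(m[g, groups == "b"], m[g, groups == "a"],
                     var.equal = TRUE)
        expect_equal(res$statistic[g], unname(tt$statistic)^2,
                     tolerance = 1e-12)
        expect_equal(res$p[g], tt$p.value, tolerance = 1e-12)
        expect_equal(res$lfc[g], unname(diff(rev(tt$estimate))),
                     tolerance = 1e-12)
    }
    ## BH adjustment equals the step-up oracle
    expect_equal(res$q, bfBH(res$p), tolerance = 1e-12)
    expect_true(res$significant[1])

    ## constant genes get p = 1 and are flagged
    m[2, ] <- 3
    res2 <- twoGroupDiff(m, groups)
    expect_true(res2$constant[2])
    expect_equal(res2$p[2], 1)

    expect_error(twoGroupDiff(m, rep(c("a", "b", "c"), length.out = 20)),
                 "two groups")
    expect_error(twoGroupDiff(m[, 1:3], c("a", "a", "b")), "2 samples")
})

test_that("the BH step-up oracle reproduces the hand-computed example", {
    p <- c(0.001, 0.01, 0.02, 0.9)
    expect_equal(bfBH(p), c(0.004, 0.02, 4 * 0.02 / 3, 0.9),
                 tolerance = 1e-12)
    expect_equal(p.adjust(p, "BH"), bfBH(p), tolerance = 1e-12)
})

test_that("a planted single-gene shift is detected among nulls", {
    hits <- vapply(1:20, function(s) {
        set.seed(s)
        m <- matrix(rnorm(1000 * 40, sd = 0.5), 1000, 40,
                    dimnames = list(paste0("g", 1:1000), paste0("s", 1:40)))
        groups <- rep(c("a", "b"), each = 20)
        m[1, groups == "b"] <- m[1, groups == "b"] + 2
        twoGroupDiff(m, groups)$q[1] < 0.05
    }, logical(1))
    expect_gte(sum(hits), 19)
})

test_that("subtype gene selection takes the union over pairwise tests", {
    rc <- generateCohort(smallConfig(seed = 8L))
    x <- correctBatch(quantileNormalise(rc))
    sel <- selectSubtypeGenes(x, trueSubtypes(rc))
    pairwise <- attr(sel, "pairwise")
    expect_length(pairwise, 3L)
    manual <- sort(unique(unlist(lapply(pairwise, function(r)
        r$gene[r$significant]))))
    expect_identical(as.character(sel), manual)

    ## planted module genes are nearly all selected
    tm <- trueModules(rc)
    expect_gte(mean(names(tm)[tm > 0] %in% sel), 0.9)

    ## under the null only alpha-level false positives appear
    set.seed(21)
    null <- matrix(rnorm(300 * 45), 300, 45,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:45)))
    selNull <- selectSubtypeGenes(null, rep(c("A", "B", "C"), each = 15))
    expect_lte(length(selNull), 15)

    expect_error(selectSubtypeGenes(null, c("A", rep(c("B", "C"), len = 44))),
                 "fewer than 2")
})

test_that("power adjacency and connectivity follow their formulas", {
    set.seed(22)
    m <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
    m[2, ] <- m[1, ] * 2 + 3            # perfectly rank-correlated pair
    net <- buildNetwork(m, beta = 4)
    S <- similarityMatrix(net); A <- adjacencyMatrix(net)
    expect_equal(A[1, 2], 1)            # |r| = 1 stays 1 under any beta
    off <- upper.tri(S)
    expect_equal(A[off], abs(S[off])^4, tolerance = 1e-12)
    expect_equal(unname(connectivity(net)),
                 unname((rowSums(A) - 1) / (nrow(A) - 1)), tolerance = 1e-12)

    ## 3-gene connectivity example via the plain-adjacency path
    A3 <- matrix(c(0, 0.2, 0.6,
                   0.2, 0, 0.5,
                   0.6, 0.5, 0), 3, 3)
    net3 <- tomDissimilarity(A3)
    expect_equal(connectivity(net3)[1], (0.2 + 0.6) / 2, tolerance = 1e-12)

    m[3, ] <- 7                          # zero-variance gene is dropped
    expect_warning(net0 <- buildNetwork(m, beta = 2), "zero-variance")
    expect_equal(nrow(adjacencyMatrix(net0)), 9L)

    expect_error(buildNetwork(m[, 1:3], beta = 2), "4 samples")
})

test_that("connectivity restriction keeps genes strictly above the cutoff", {
    mk <- function(conn) new("NetworkMatrices",
        similarity = diag(4), adjacency = diag(4),
        connectivity = conn, tom = matrix(numeric(0), 0, 0), beta = 6)
    net <- mk(c(0.05, 0.1, 0.2, 0.3))
    ## median = 0.15; strict > keeps the top two
    kept <- restrictByConnectivity(net, cutoff = "median")
    expect_equal(unname(connectivity(kept)), c(0.2, 0.3))
    ## the explicit 0.1 cutoff keeps the same two genes
    kept2 <- restrictByConnectivity(net, cutoff = 0.1)
    expect_equal(unname(connectivity(kept2)), c(0.2, 0.3))
    ## all-equal connectivity: strict inequality removes everything
    expect_error(restrictByConnectivity(mk(rep(0.2, 4))), "fewer than 2")
})

test_that("TOM dissimilarity matches hand values and the brute-force oracle", {
    ## 2-gene network: no shared neighbours, K = a = 0.8
    A2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
    D2 <- tomDiss(tomDissimilarity(A2))
    expect_equal(D2[1, 2], 0.2, tolerance = 1e-12)

    ## identical binary rows with a_ij = 1: maximal overlap, D = 0
    Ab <- matrix(0, 4, 4)
    Ab[1, 2] <- Ab[2, 1] <- 1
    Ab[1, 3] <- Ab[3, 1] <- 1; Ab[2, 3] <- Ab[3, 2] <- 1
    Db <- tomDiss(tomDissimilarity(Ab))
    expect_equal(Db[1, 2], 0, tolerance = 1e-12)

    ## random 6-gene adjacency equals the triple-loop evaluation
    set.seed(23)
    A6 <- matrix(runif(36), 6, 6); A6 <- (A6 + t(A6)) / 2; diag(A6) <- 1
    D6 <- tomDiss(tomDissimilarity(A6))
    expect_equal(unname(D6), bfTOM(A6), tolerance = 1e-12)
    expect_true(all(D6 >= 0 & D6 <= 1))

    ## permutation equivariance
    p <- sample(6)
    Dp <- tomDiss(tomDissimilarity(A6[p, p]))
    expect_equal(unname(Dp), unname(D6[p, p]), tolerance = 1e-12)

    expect_error(tomDissimilarity(matrix(c(0, 2, 2, 0), 2, 2)), "symmetric")
})
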
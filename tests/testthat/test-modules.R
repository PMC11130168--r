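## block-structured TOM-like dissimilarity: low within blocks, high between
blockDiss <- function(sizes, within = 0.2, between = 0.95, seed = 1L) {
    set.seed(seed)
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    D <- matrix(between, n, n)
    D[outer(lab, lab, "==")] <- within
    D <- D + matrix(runif(n * n, 0, 0.01), n, n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
    list(D = D, lab = lab)
}

test_that("two perfectly separated blocks give exactly two modules", {
    ## exact zero/one distances: tied merges must not be split arbitrarily
    n <- 20
    lab <- rep(1:2, each = 10)
    D <- matrix(1, n, n)
    D[outer(lab, lab, "==")] <- 0
    diag(D) <- 0
    dimnames(D) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    for (method in c("sweep", "stability")) {
        for (sf in c(0.5, 0.8, 1.0)) {
            ms <- treeCutModules(D, method = method, stabilityFrac = sf)
            expect_length(moduleList(ms), 2L)
            expect_setequal(moduleList(ms)$M01, rownames(D)[lab == lab[1]])
        }
    }
})

test_that("noisy planted blocks are recovered and small ones left out", {
    b <- blockDiss(c(20, 15, 10, 4), seed = 2)
    ms <- treeCutModules(b$D, kMin = 3, kMax = 30, minSize = 5)
    expect_equal(unname(moduleSizes(ms)), c(20L, 15L, 10L))
    ## the 4-gene block falls under minSize and is unassigned
    expect_setequal(unassignedGenes(ms), rownames(b$D)[b$lab == 4])
    ## partitions agree with the planted labels
    ml <- moduleLabelsOf(ms)
    big <- names(ml)
    expect_equal(length(unique(paste(ml, b$lab[match(big, rownames(b$D))]))),
                 3L)
    expect_error(treeCutModules(b$D, kMin = 3, kMax = 30, minSize = 25),
                 "minSize")
})

test_that("enrichment pruning applies the urn model and the size floor", {
    genes <- sprintf("g%03d", 1:100)
    ms <- new("GeneModuleSet",
              modules = list(M01 = genes[1:10], M02 = genes[11:16]),
              unassigned = genes[17:100], provenance = list())

    sets <- list(hitSet = genes[1:10],           # identical to M01
                 halfSet = genes[c(6:10, 90:94)],
                 partM02 = c(genes[11:14], genes[40:45]))
    res <- enrichmentPrune(ms, sets, alpha = 0.05, minSize = 5)
    enr <- provenance(res)$enrichment

    ## hypergeometric tail equals direct summation
    p12 <- enr$p[enr$module == "M01" & enr$geneSet == "halfSet"]
    expect_equal(p12, bfHyperTail(5, 10, 100, 10), tolerance = 1e-12)
    pFull <- enr$p[enr$module == "M01" & enr$geneSet == "hitSet"]
    expect_equal(pFull, bfHyperTail(10, 10, 100, 10), tolerance = 1e-12)

    ## a module identical to a significant set is retained intact
    expect_true(any(vapply(moduleList(res), function(g)
        setequal(g, genes[1:10]), logical(1))))
    ## M02: only 4 of 6 genes sit in its significant set -> below floor,
    ## dropped entirely
    expect_false(any(vapply(moduleList(res), function(g)
        any(g %in% genes[11:16]), logical(1))))

    ## gene-set members outside the universe are ignored with a warning
    expect_warning(enrichmentPrune(ms, list(s = c(genes[1:8], "alien"))),
                   "absent")
    expect_error(enrichmentPrune(ms, list()), "non-empty")
})

test_that("module TSV round trip preserves the partition", {
    b <- blockDiss(c(12, 8), seed = 3)
    ms <- treeCutModules(b$D, kMin = 2, kMax = 10, minSize = 5)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeModules(ms, f)
    expect_true(file.exists(sub("\\.tsv$", ".json", f)))
    back <- readModules(f)
    expect_identical(moduleList(back), moduleList(ms))
    expect_setequal(unassignedGenes(back), unassignedGenes(ms))
})

test_that("planted expression modules survive the full network stage", {
    rc <- generateCohort(smallConfig(seed = 9L, effect = 1.0))
    x <- correctBatch(quantileNormalise(rc))
    sel <- selectSubtypeGenes(x, trueSubtypes(rc))
    net <- buildNetwork(x, genes = sel)
    net <- restrictByConnectivity(net, cutoff = "bimodal")
    net <- tomDissimilarity(net)
    ms <- treeCutModules(net, kMin = 2, kMax = 30)
    tm <- trueModules(rc)
    jac <- vapply(1:3, function(m) jaccardBestMatch(ms, tm, m), numeric(1))
    expect_true(all(jac >= 0.7))
})

test_that("module recovery does not degrade as the subtype effect grows", {
    jacAt <- function(effect, seed) {
        rc <- generateCohort(smallConfig(seed = seed, effect = effect))
        x <- correctBatch(quantileNormalise(rc))
        sel <- selectSubtypeGenes(x, trueSubtypes(rc))
        if (length(sel) < 10) return(0)  # no recoverable signal selected
        net <- tomDissimilarity(
            restrictByConnectivity(buildNetwork(x, genes = sel), "bimodal"))
        ms <- treeCutModules(net, kMin = 2, kMax = 30)
        tm <- trueModules(rc)
        mean(vapply(1:3, function(m) jaccardBestMatch(ms, tm, m), numeric(1)))
    }
    for (s in 1:2) {
        j <- vapply(c(0.5, 1.0, 2.0), jacAt, numeric(1), seed = s)
        expect_true(all(diff(j) > -0.05))
    }
})
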
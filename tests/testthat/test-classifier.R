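mkModuleSet <- function(mods) {
    new("GeneModuleSet", modules = mods, unassigned = character(0),
        provenance = list())
}

test_that("module medians follow the median convention and track coverage", {
    m <- matrix(c(1, 2, 10, 1, 2, 3, 4,
                  5, 6, 7, 8, 9, 10, 11), 7, 2,
                dimnames = list(paste0("g", 1:7), c("s1", "s2")))
    ms <- mkModuleSet(list(M01 = c("g1", "g2", "g3"),
                           M02 = paste0("g", 4:7)))
    sc <- moduleMedians(m, ms, standardise = FALSE)
    expect_equal(scoreMatrix(sc)["s1", "M01"], 2)          # odd size
    expect_equal(scoreMatrix(sc)["s1", "M02"], 2.5)        # even: mid-mean
    expect_equal(unname(moduleCoverage(sc)), c(1, 1))

    ## half the module's genes missing: recomputed on the rest, coverage 0.5
    sc2 <- moduleMedians(m[c("g1", "g2", "g4", "g5"), ], ms,
                         standardise = FALSE)
    expect_equal(scoreMatrix(sc2)["s1", "M01"], 1.5)
    expect_equal(scoreMatrix(sc2)["s1", "M02"], 1.5)
    expect_equal(unname(moduleCoverage(sc2)), c(2 / 3, 0.5))

    expect_error(moduleMedians(m[c("g1", "g4"), ], ms, minCoverage = 0.9),
                 "coverage floor")
    expect_error(moduleMedians(m, mkModuleSet(list(M01 = c("x1", "x2")))),
                 "no overlap")
})

test_that("a separable problem is classified perfectly in every fold", {
    ## separable with duplicated boundary values, so every split point is
    ## represented in the training part of each fold
    set.seed(30)
    sc <- cbind(f1 = c(rep(c(0, 1), 10), rep(c(9, 10), 10)),
                f2 = rnorm(40, 0, 0.1))
    rownames(sc) <- sprintf("s%02d", 1:40)
    lab <- rep(c("lo", "hi"), each = 20)
    mod <- trainSubtypeModel(sc, lab, folds = 5, seed = 1, nrounds = 50)
    expect_true(all(cvMetrics(mod)$accuracy == 1))
    expect_true(all(mod@cvAUC == 1))
    expect_error(trainSubtypeModel(sc[1:23, ], lab[1:23], folds = 5),
                 "hi")
})

test_that("shuffled labels drive CV accuracy to chance", {
    set.seed(31)
    sc <- matrix(rnorm(60 * 4), 60, 4,
                 dimnames = list(sprintf("s%02d", 1:60), paste0("f", 1:4)))
    lab <- sample(rep(c("A", "B", "C"), each = 20))
    mod <- trainSubtypeModel(sc, lab, folds = 5, seed = 2, nrounds = 50)
    expect_lt(abs(mean(cvMetrics(mod)$accuracy) - 1 / 3), 0.15)
})

test_that("training is deterministic and predictions are proper", {
    rc <- generateCohort(smallConfig(seed = 13L))
    x <- correctBatch(quantileNormalise(rc))
    tm <- trueModules(rc)
    ms <- mkModuleSet(split(names(tm)[tm > 0], paste0("M0", tm[tm > 0])))
    sc <- moduleMedians(x, ms)
    m1 <- trainSubtypeModel(sc, trueSubtypes(rc), seed = 7, nrounds = 60,
                            moduleSet = ms)
    m2 <- trainSubtypeModel(sc, trueSubtypes(rc), seed = 7, nrounds = 60,
                            moduleSet = ms)
    expect_identical(m1@boosterRaw, m2@boosterRaw)
    expect_identical(cvMetrics(m1), cvMetrics(m2))

    pred <- predictSubtypes(m1, x)
    probs <- as.matrix(pred[, modelClasses(m1)])
    expect_true(all(probs >= 0))
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
    ## in-sample predictions reproduce the training labels
    expect_gte(mean(pred$label == trueSubtypes(rc)), 0.99)

    ## row order of the gene matrix is irrelevant (ID-keyed features)
    perm <- sample(nrow(x))
    predPerm <- predictSubtypes(m1, exprsMatrix(x)[perm, ])
    expect_identical(predPerm$label, pred$label)

    ## robustness: 30% of genes dropped at random
    set.seed(32)
    keep <- sample(rownames(x), round(0.7 * nrow(x)))
    predDrop <- predictSubtypes(m1, exprsMatrix(x)[keep, ])
    expect_gte(mean(predDrop$label == pred$label), 0.9)
})

test_that("the model archive round-trips exactly", {
    rc <- generateCohort(smallConfig(seed = 14L))
    x <- correctBatch(quantileNormalise(rc))
    tm <- trueModules(rc)
    ms <- mkModuleSet(split(names(tm)[tm > 0], paste0("M0", tm[tm > 0])))
    mod <- trainSubtypeModel(moduleMedians(x, ms), trueSubtypes(rc),
                             seed = 3, nrounds = 60, moduleSet = ms)
    f <- withr::local_tempfile(fileext = ".json")
    saveSubtypeModel(mod, f)
    back <- readSubtypeModel(f)
    expect_identical(back@boosterRaw, mod@boosterRaw)
    expect_identical(modelClasses(back), modelClasses(mod))
    expect_equal(cvMetrics(back), cvMetrics(mod))
    expect_identical(moduleList(moduleSet(back)), moduleList(moduleSet(mod)))
    expect_identical(predictSubtypes(back, x), predictSubtypes(mod, x))
    bogus <- withr::local_tempfile(fileext = ".json")
    writeLines('{"format": "something-else"}', bogus)
    expect_error(readSubtypeModel(bogus), "not a SubtypeModel archive")
})

test_that("label noise degrades CV accuracy monotonically", {
    accAt <- function(flip, seed) {
        rc <- generateCohort(smallConfig(seed = seed))
        x <- correctBatch(quantileNormalise(rc))
        tm <- trueModules(rc)
        ms <- mkModuleSet(split(names(tm)[tm > 0], paste0("M0", tm[tm > 0])))
        lab <- trueSubtypes(rc)
        set.seed(seed + 100)
        idx <- sample(length(lab), round(flip * length(lab)))
        lab[idx] <- sample(c("S1", "S2", "S3"), length(idx), replace = TRUE)
        mod <- trainSubtypeModel(moduleMedians(x, ms), lab, seed = 1,
                                 nrounds = 60)
        mean(cvMetrics(mod)$accuracy)
    }
    for (s in 1:3) {
        acc <- vapply(c(0, 0.1, 0.3), accAt, numeric(1), seed = s)
        expect_true(all(diff(acc) <= 0.02))
    }
})
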
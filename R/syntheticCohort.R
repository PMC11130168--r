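#' Default planted subtype-effect matrix
#'
#' Builds a modules x subtypes matrix of log2 mean shifts in which module m is
#' up-regulated (by `effect`) in exactly one subtype, cycling through the
#' subtypes so each subtype owns roughly the same number of signature
#' modules. This mirrors the structure of transcriptional subtypes driven by
#' distinct gene programmes (e.g. a stromal/EMT programme versus a
#' proliferative one).
#'
#' @param nModules number of planted modules.
#' @param nSubtypes number of planted subtypes.
#' @param effect log2 shift applied to a module in its signature subtype.
#' @return numeric matrix, `nModules` x `nSubtypes`.
#' @export
defaultSubtypeEffects <- function(nModules = 12L, nSubtypes = 3L, effect = 1.0) {
    eff <- matrix(0, nModules, nSubtypes)
    for (m in seq_len(nModules))
        eff[m, ((m - 1L) %% nSubtypes) + 1L] <- effect
    dimnames(eff) <- list(paste0("M", seq_len(nModules)),
                          paste0("S", seq_len(nSubtypes)))
    eff
}

#' Synthetic cohort configuration
#'
#' Defines the generative model for a synthetic expression cohort:
#' `nGenes` genes of which `sum(moduleSizes)` belong to block-correlated
#' modules, `nSubtypes` planted subtypes shifting module means by
#' `subtypeEffects`, `nBatches` batches with additive and multiplicative
#' gene-wise effects, exponential survival with per-subtype hazards and
#' uniform censoring, and an additive post-treatment activation of the
#' `stromalModules`.
#'
#' Defaults describe a cohort of 180 samples and 2000 genes with 12 modules
#' of 20-120 genes, 3 balanced subtypes each owning a third of the modules at
#' a 1.0 log2 shift, and 4 batches — the scale of a merged multi-study
#' microarray compendium after restriction to one tissue.
#'
#' @param nSamples number of samples.
#' @param nGenes number of genes.
#' @param moduleSizes integer vector of module sizes; their sum must not
#'   exceed `nGenes`; remaining genes are uncorrelated background.
#' @param nSubtypes number of planted subtypes.
#' @param subtypeEffects modules x subtypes matrix of log2 mean shifts;
#'   default [defaultSubtypeEffects()] with `effect`.
#' @param effect convenience scalar used to build `subtypeEffects` when that
#'   matrix is not supplied.
#' @param stromalModules indices of the modules regarded as stromal; by
#'   default the signature modules of the last subtype, which plays the role
#'   of the mesenchymal/stromal group that post-treatment samples shift
#'   towards.
#' @param withinModuleCor target mean pairwise Spearman correlation between
#'   genes of one module, attained through a common latent-factor loading
#'   calibrated against the noise level (subtype and batch effects add to or
#'   subtract from the realised correlation slightly).
#' @param nBatches number of batches.
#' @param batchShiftSd sd of additive per-(gene, batch) log2 offsets.
#' @param batchScaleSd sd (log scale) of multiplicative per-(gene, batch)
#'   scalings of the biological + noise component.
#' @param noiseSd sd of iid log2 measurement noise.
#' @param baselineMean,baselineSd mean/sd of per-gene baseline log2 intensity.
#' @param hazards per-subtype exponential event rate, 1/month.
#' @param censorWindow months; censoring times are uniform on (0, window].
#' @param shiftEffect log2 units added to stromal-module genes in
#'   post-treatment samples by [generateTreatmentPairs()].
#' @param seed integer seed; fixing it reproduces the cohort bit-identically.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nSamples = 60, nGenes = 300, moduleSizes = c(30, 20, 20))
#' @export
cohortConfig <- function(nSamples = 180L, nGenes = 2000L,
                         moduleSizes = c(120L, 100L, 90L, 80L, 70L, 60L,
                                         50L, 40L, 35L, 30L, 25L, 20L),
                         nSubtypes = 3L, effect = 1.0,
                         subtypeEffects = defaultSubtypeEffects(
                             length(moduleSizes), nSubtypes, effect),
                         stromalModules = which(
                             subtypeEffects[, nSubtypes] ==
                                 apply(subtypeEffects, 1, max) &
                             apply(abs(subtypeEffects), 1, max) >= 0),
                         withinModuleCor = 0.7, nBatches = 4L,
                         batchShiftSd = 0.3, batchScaleSd = 0.1,
                         noiseSd = 0.25, baselineMean = 7, baselineSd = 1,
                         hazards = c(0.02, 0.05, 0.03), censorWindow = 120,
                         shiftEffect = 1.5, seed = 1L) {
    if (sum(moduleSizes) > nGenes)
        stop("configuration error: sum(moduleSizes) = ", sum(moduleSizes),
             " exceeds nGenes = ", nGenes)
    if (length(hazards) == 1L) hazards <- rep(hazards, nSubtypes)
    new("CohortConfig",
        nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
        nModules = length(moduleSizes), moduleSizes = as.integer(moduleSizes),
        nSubtypes = as.integer(nSubtypes),
        subtypeEffects = as.matrix(subtypeEffects),
        stromalModules = as.integer(stromalModules),
        withinModuleCor = withinModuleCor, nBatches = as.integer(nBatches),
        batchShiftSd = batchShiftSd, batchScaleSd = batchScaleSd,
        noiseSd = noiseSd, baselineMean = baselineMean, baselineSd = baselineSd,
        hazards = hazards, censorWindow = censorWindow,
        shiftEffect = shiftEffect, seed = as.integer(seed))
}

## latent-factor loading giving the target within-module Spearman correlation
## against iid noise: rho_pearson = 2 sin(pi rho_s / 6) inverts the normal
## rank-correlation attenuation, then w^2 / (w^2 + sd^2) = rho_pearson.
.moduleLoading <- function(targetSpearman, noiseSd) {
    if (noiseSd == 0) return(0)
    rhoP <- 2 * sin(pi * targetSpearman / 6)
    noiseSd * sqrt(rhoP / (1 - rhoP))
}

## core sampler shared by generateCohort and generateTreatmentPairs; assumes
## the RNG state has been set by the caller.
.simulateExpression <- function(config, subtypes, batches, sampleIds) {
    n <- length(subtypes)
    g <- config@nGenes
    geneIds <- sprintf("g%04d", seq_len(g))
    moduleOf <- integer(g)
    if (config@nModules > 0)
        moduleOf[seq_len(sum(config@moduleSizes))] <-
            rep(seq_len(config@nModules), times = config@moduleSizes)

    mu <- stats::rnorm(g, config@baselineMean, config@baselineSd)
    w <- .moduleLoading(config@withinModuleCor, config@noiseSd)

    ## latent module factors, one draw per (module, sample)
    fac <- matrix(stats::rnorm(config@nModules * n), config@nModules, n)
    signal <- matrix(0, g, n)
    inMod <- moduleOf > 0
    if (any(inMod)) {
        signal[inMod, ] <- w * fac[moduleOf[inMod], , drop = FALSE]
        signal[inMod, ] <- signal[inMod, ] +
            config@subtypeEffects[moduleOf[inMod], subtypes, drop = FALSE]
    }
    noise <- matrix(stats::rnorm(g * n, 0, config@noiseSd), g, n)

    shift <- matrix(stats::rnorm(g * config@nBatches, 0, config@batchShiftSd),
                    g, config@nBatches)
    scale <- matrix(exp(stats::rnorm(g * config@nBatches, 0, config@batchScaleSd)),
                    g, config@nBatches)

    x <- mu + scale[, batches, drop = FALSE] * (signal + noise) +
        shift[, batches, drop = FALSE]
    dimnames(x) <- list(geneIds, sampleIds)
    list(exprs = x, moduleOf = moduleOf, mu = mu)
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Draws a log2 expression matrix
#' \deqn{x_{gs} = \mu_g + s_{g,b(s)} (w f_{m(g),s} + \delta_{m(g),c(s)} +
#'   e_{gs}) + a_{g,b(s)}}
#' with per-module latent factors f (standard normal per module and sample),
#' a common loading w calibrated to the target within-module correlation,
#' subtype mean shifts \eqn{\delta} from the effect matrix, additive batch
#' offsets a and multiplicative batch scalings s, and iid noise e. Background
#' genes (not in any module) carry no factor and no subtype shift. Survival
#' times are exponential with the subtype's hazard, censored uniformly on
#' (0, censorWindow].
#'
#' Subtypes and batches are assigned in a balanced, randomly permuted
#' fashion. The result is bit-identical for a fixed `seed`.
#'
#' @param config a [cohortConfig()] object.
#' @return a [RectalCohort-class] whose `colData` carries batch, planted
#'   subtype, follow-up (`time_months`, `event`) and TNM-style staging
#'   fields, and whose `rowData` carries the planted module of each gene
#'   (0 = background).
#' @examples
#' rc <- generateCohort(cohortConfig(nSamples = 30, nGenes = 200,
#'                                   moduleSizes = c(20, 15, 10)))
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nSamples

    subtypes <- sample(rep_len(seq_len(config@nSubtypes), n))
    batches <- sample(rep_len(seq_len(config@nBatches), n))
    sampleIds <- sprintf("s%04d", seq_len(n))

    sim <- .simulateExpression(config, subtypes, batches, sampleIds)

    ## survival: exponential event times, uniform censoring
    tEvent <- stats::rexp(n, rate = config@hazards[subtypes])
    tCens <- stats::runif(n, 0, config@censorWindow)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)

    ## TNM-style staging with partially missing overall stage
    tStage <- sample(1:4, n, replace = TRUE, prob = c(0.1, 0.3, 0.45, 0.15))
    nStage <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.35, 0.2))
    mStage <- stats::rbinom(n, 1, 0.12)
    stage <- ifelse(mStage == 1, 4L,
                    ifelse(nStage > 0, 3L, ifelse(tStage >= 3, 2L, 1L)))
    stage[sample.int(n, round(0.35 * n))] <- NA_integer_

    cd <- data.frame(
        batch = paste0("batch", batches),
        true_subtype = paste0("S", subtypes),
        tissue = "rectum", treatment = "naive",
        time_months = time, event = event,
        T = tStage, N = nStage, M = mStage, stage = stage,
        pair_key = NA_character_,
        row.names = sampleIds, check.names = FALSE)
    rd <- data.frame(true_module = sim$moduleOf,
                     row.names = rownames(sim$exprs))
    RectalCohort(sim$exprs, batch = cd$batch, colData = cd, rowData = rd,
                 metadata = list(config = config))
}

#' Generate matched pre/post-treatment sample pairs
#'
#' Simulates `nPairs` pre-treatment samples from the cohort model, then
#' builds each post-treatment partner by adding `shiftEffect` log2 units to
#' every gene of the stromal modules plus fresh measurement noise — an
#' additive stromal activation of the kind neoadjuvant chemoradiotherapy
#' induces via fibroblast expansion. The pairing is recorded in the
#' `pair_key` column.
#'
#' @param config a [cohortConfig()] with at least one stromal module.
#' @param nPairs number of pre/post pairs (> 0).
#' @return a [RectalCohort-class] with `2 * nPairs` samples; `colData`
#'   carries `timepoint` ("pre"/"post") and `pair_key`.
#' @export
generateTreatmentPairs <- function(config, nPairs = 50L) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    if (nPairs <= 0) stop("nPairs must be > 0")
    if (length(config@stromalModules) == 0)
        stop("config must designate at least one stromal module")
    set.seed(config@seed + 104729L)  # distinct stream from generateCohort

    subtypes <- sample(rep_len(seq_len(config@nSubtypes), nPairs))
    batches <- sample(rep_len(seq_len(config@nBatches), nPairs))
    keys <- sprintf("P%03d", seq_len(nPairs))

    pre <- .simulateExpression(config, subtypes, batches,
                               paste0(keys, "_pre"))
    stromalGenes <- pre$moduleOf %in% config@stromalModules
    post <- pre$exprs +
        config@shiftEffect * stromalGenes +
        matrix(stats::rnorm(length(pre$exprs), 0, config@noiseSd),
               nrow(pre$exprs))
    colnames(post) <- paste0(keys, "_post")

    exprs <- cbind(pre$exprs, post)
    cd <- data.frame(
        batch = rep(paste0("batch", batches), 2),
        true_subtype = rep(paste0("S", subtypes), 2),
        timepoint = rep(c("pre", "post"), each = nPairs),
        treatment = rep(c("naive", "CRT"), each = nPairs),
        pair_key = rep(keys, 2),
        row.names = colnames(exprs), check.names = FALSE)
    rd <- data.frame(true_module = pre$moduleOf,
                     row.names = rownames(exprs))
    RectalCohort(exprs, batch = cd$batch, colData = cd, rowData = rd,
                 metadata = list(config = config, nPairs = as.integer(nPairs)))
}
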
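## cut a dendrogram into (at most) k clusters by height: the cut is placed
## just above the (n-k)-th lowest merge, so tied merge heights are treated
## as a unit and degenerate trees (many zero-height merges) fall back to
## their natural cluster structure instead of arbitrary tie splits.
.cutAtK <- function(hc, k) {
    n <- length(hc$height) + 1L
    if (k >= n) return(stats::cutree(hc, k = n))
    if (k <= 1) return(rep(1L, n))
    h <- hc$height[n - k]
    stats::cutree(hc, h = h)
}

## vectorised mean silhouette width of a labelling on a distance matrix
.meanSilhouette <- function(d, labels) {
    labels <- as.integer(factor(labels))
    k <- max(labels)
    if (k < 2) return(-Inf)
    n <- nrow(d)
    ind <- matrix(0, n, k)
    ind[cbind(seq_len(n), labels)] <- 1
    sizes <- colSums(ind)
    sums <- d %*% ind
    own <- sums[cbind(seq_len(n), labels)]
    a <- own / pmax(sizes[labels] - 1, 1)
    avg <- sweep(sums, 2, sizes, "/")
    avg[cbind(seq_len(n), labels)] <- Inf
    b <- do.call(pmin, as.data.frame(avg))
    s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
    s[sizes[labels] == 1] <- 0
    mean(s)
}

#' Detect gene modules by sweeping dendrogram cuts
#'
#' Clusters genes by average linkage on the topological overlap
#' dissimilarity and sweeps cut levels from `kMin` to `kMax` clusters
#' (height-based cuts, so tied merges are never split arbitrarily). Two
#' constructions of the final partition are available:
#'
#' * `"sweep"` (default): every cut is scored by its mean silhouette width
#'   on D and the best-scoring cut is kept; its clusters of at least
#'   `minSize` genes become the modules.
#' * `"stability"`: gene pairs co-assigned in at least `stabilityFrac` of
#'   all cuts are linked, and the connected components of that graph of at
#'   least `minSize` genes become the modules.
#'
#' In both cases genes in sub-threshold components are left unassigned and
#' modules are ordered by decreasing size (`M01`, `M02`, ...).
#'
#' @param D topological overlap dissimilarity matrix (or a
#'   [NetworkMatrices-class] whose TOM slot is filled).
#' @param kMin,kMax range of cut levels (defaults 5 and 101); `kMax` is
#'   clamped to the number of genes minus 1.
#' @param minSize smallest module retained (default 5).
#' @param method `"sweep"` or `"stability"` (see above).
#' @param stabilityFrac co-assignment frequency defining a stable pair
#'   (default 0.8; `"stability"` method only).
#' @return a [GeneModuleSet-class] with the sweep parameters in
#'   `provenance`.
#' @importFrom igraph graph_from_adjacency_matrix components
#' @export
treeCutModules <- function(D, kMin = 5L, kMax = 101L, minSize = 5L,
                           method = c("sweep", "stability"),
                           stabilityFrac = 0.8) {
    method <- match.arg(method)
    if (is(D, "NetworkMatrices")) {
        if (!length(tomDiss(D))) stop("run tomDissimilarity() first")
        D <- tomDiss(D)
    }
    D <- .checkDist(D)
    n <- nrow(D)
    genes <- rownames(D)
    if (is.null(genes)) genes <- paste0("g", seq_len(n))
    kMax <- min(kMax, n - 1L)
    if (kMin > kMax) stop("kMin exceeds the feasible cut range")
    ks <- seq.int(kMin, kMax)
    hc <- stats::hclust(stats::as.dist(D), method = "average")

    cuts <- lapply(ks, function(k) .cutAtK(hc, k))
    if (method == "sweep") {
        sil <- vapply(cuts, function(lab) .meanSilhouette(D, lab), numeric(1))
        best <- which.max(sil)
        labels <- cuts[[best]]
        chosen <- list(k = ks[best], meanSilhouette = sil[best])
    } else {
        freq <- matrix(0, n, n)
        for (lab in cuts) freq <- freq + outer(lab, lab, "==")
        freq <- freq / length(cuts)
        g <- igraph::graph_from_adjacency_matrix(freq >= stabilityFrac,
                                                 mode = "undirected",
                                                 diag = FALSE)
        labels <- igraph::components(g)$membership
        chosen <- list(stabilityFrac = stabilityFrac)
    }

    sizes <- table(labels)
    keepCl <- names(sizes)[sizes >= minSize]
    if (!length(keepCl))
        stop("no module of at least ", minSize, " genes found; consider a ",
             "smaller minSize",
             if (method == "stability") " or a lower stabilityFrac" else "")
    keepCl <- keepCl[order(-sizes[keepCl])]
    modules <- lapply(keepCl, function(cl) genes[labels == cl])
    names(modules) <- sprintf("M%02d", seq_along(modules))
    unassigned <- setdiff(genes, unlist(modules))
    new("GeneModuleSet", modules = modules, unassigned = unassigned,
        provenance = c(list(method = method, kMin = kMin, kMax = kMax,
                            minSize = minSize), chosen))
}

#' Read a GMT gene-set collection
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return named list of gene identifier vectors.
#' @export
readGMT <- function(path) {
    fgsea::gmtPathways(path)
}

#' Prune modules by gene-set over-representation
#'
#' Tests every module x gene-set pair with a one-sided hypergeometric
#' over-representation test against the universe of all network genes,
#' adjusts with BH across all pairs, then keeps within each module only the
#' genes belonging to at least one gene set significant for that module.
#' Modules falling below `minSize` genes are dropped entirely. Gene-set
#' members absent from the universe are ignored with a warning.
#'
#' @param modules a [GeneModuleSet-class].
#' @param geneSets named list of gene vectors (see [readGMT()]).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param minSize smallest module retained after pruning (default 5).
#' @return the pruned [GeneModuleSet-class]; the enrichment table is stored
#'   in `provenance(x)$enrichment`.
#' @export
enrichmentPrune <- function(modules, geneSets, alpha = 0.05, minSize = 5L) {
    stopifnot(is(modules, "GeneModuleSet"))
    if (!length(geneSets)) stop("'geneSets' must be non-empty")
    universe <- c(unlist(moduleList(modules)), unassignedGenes(modules))
    N <- length(universe)

    lost <- setdiff(unique(unlist(geneSets)), universe)
    if (length(lost))
        warning(length(lost), " gene-set member(s) absent from the network ",
                "universe were ignored")
    geneSets <- lapply(geneSets, intersect, universe)

    mods <- moduleList(modules)
    rows <- list()
    for (mn in names(mods)) {
        mod <- mods[[mn]]
        for (sn in names(geneSets)) {
            set <- geneSets[[sn]]
            ov <- length(intersect(mod, set))
            p <- stats::phyper(ov - 1, length(set), N - length(set),
                               length(mod), lower.tail = FALSE)
            rows[[length(rows) + 1L]] <-
                data.frame(module = mn, geneSet = sn, overlap = ov,
                           setSize = length(set), moduleSize = length(mod),
                           p = p)
        }
    }
    enr <- do.call(rbind, rows)
    enr$q <- stats::p.adjust(enr$p, method = "BH")
    enr$significant <- enr$q < alpha

    kept <- list()
    for (mn in names(mods)) {
        sigSets <- enr$geneSet[enr$module == mn & enr$significant]
        inSig <- unique(unlist(geneSets[sigSets]))
        remaining <- intersect(mods[[mn]], inSig)
        if (length(remaining) >= minSize) kept[[mn]] <- remaining
    }
    if (length(kept)) {
        kept <- kept[order(-vapply(kept, length, integer(1)))]
        names(kept) <- sprintf("M%02d", seq_along(kept))
    }
    unassigned <- setdiff(universe, unlist(kept))
    new("GeneModuleSet", modules = kept, unassigned = unassigned,
        provenance = c(provenance(modules),
                       list(enrichment = enr, enrichmentAlpha = alpha,
                            enrichmentMinSize = minSize)))
}

#' Write / read a module partition as a two-column TSV
#'
#' The TSV has columns `gene` and `module` (unassigned genes carry module
#' `"unassigned"`); a JSON provenance sidecar records the parameters used.
#'
#' @param modules a [GeneModuleSet-class].
#' @param file output TSV path.
#' @param provenanceFile optional JSON sidecar path (default: `file` with a
#'   `.json` extension).
#' @return `file`, invisibly.
#' @export
writeModules <- function(modules, file, provenanceFile = NULL) {
    stopifnot(is(modules, "GeneModuleSet"))
    mods <- moduleList(modules)
    df <- data.frame(
        gene = c(unlist(mods, use.names = FALSE), unassignedGenes(modules)),
        module = c(rep(names(mods), lengths(mods)),
                   rep("unassigned", length(unassignedGenes(modules)))))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(provenanceFile))
        provenanceFile <- paste0(sub("\\.tsv$", "", file), ".json")
    prov <- provenance(modules)
    prov <- prov[!vapply(prov, is.data.frame, logical(1))]
    jsonlite::write_json(prov, provenanceFile, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' @rdname writeModules
#' @export
readModules <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    mods <- split(df$gene, df$module)
    unassigned <- as.character(mods[["unassigned"]])
    mods[["unassigned"]] <- NULL
    mods <- mods[order(-vapply(mods, length, integer(1)), names(mods))]
    new("GeneModuleSet", modules = mods,
        unassigned = if (is.null(unassigned)) character(0) else unassigned,
        provenance = list(source = file))
}
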
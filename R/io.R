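#' Read and write expression matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column (`gene`)
#' holds gene identifiers and whose remaining columns are samples, values
#' on the log2 scale.
#'
#' @param x a [RectalCohort-class] or genes x samples matrix.
#' @param file path to the TSV.
#' @return `writeExpressionTSV`: `file`, invisibly. `readExpressionTSV`: a
#'   numeric matrix with gene rownames and sample colnames.
#' @export
writeExpressionTSV <- function(x, file) {
    m <- .getExprs(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(file) {
    df <- utils::read.delim(file, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in ", file)
    storage.mode(m) <- "double"
    m
}

#' Export a cohort's sample annotation (and truth, if simulated) as CSV
#'
#' @param x a [RectalCohort-class].
#' @param file path to the CSV; samples become rows with a `sample_id`
#'   column.
#' @return `file`, invisibly.
#' @export
writeAnnotationCSV <- function(x, file) {
    stopifnot(is(x, "RectalCohort"))
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    df <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE,
                     row.names = NULL)
    utils::write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' @rdname writeAnnotationCSV
#' @export
readAnnotationCSV <- function(file) {
    utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Export a full cohort (expression TSV + annotation CSV + gene truth CSV)
#'
#' @param x a [RectalCohort-class].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix (default `"cohort"`).
#' @return named character vector of the written paths.
#' @export
exportCohort <- function(x, dir, prefix = "cohort") {
    stopifnot(is(x, "RectalCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        expression = file.path(dir, paste0(prefix, "_expression.tsv")),
        annotation = file.path(dir, paste0(prefix, "_annotation.csv")))
    writeExpressionTSV(x, paths[["expression"]])
    writeAnnotationCSV(x, paths[["annotation"]])
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    if (ncol(rd)) {
        paths[["gene_truth"]] <- file.path(dir, paste0(prefix, "_genes.csv"))
        utils::write.csv(data.frame(gene = rownames(x), rd, row.names = NULL),
                         paths[["gene_truth"]], row.names = FALSE)
    }
    paths
}
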
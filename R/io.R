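#' Read a delimited gene-expression matrix
#'
#' Expects a header line of condition identifiers and one row per gene with
#' its identifier in the first column. Missing cells (the `missingToken`)
#' are handled by the chosen policy: `"reject"` (default) aborts naming the
#' offending cells, `"mean"` imputes each missing cell with the gene's row
#' mean over its present values.
#'
#' @param path input file.
#' @param delimiter field delimiter (default tab).
#' @param missingToken string marking a missing value (default `"NA"`).
#' @param missingPolicy `"reject"` or `"mean"`.
#' @return a numeric matrix with gene ids as rownames and condition ids as
#'   colnames; every entry finite.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, delimiter = "\t", missingToken = "NA",
                                 missingPolicy = c("reject", "mean")) {
    missingPolicy <- match.arg(missingPolicy)
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
        row.names = 1L, check.names = FALSE, na.strings = missingToken,
        colClasses = NA, comment.char = "")
    if (anyDuplicated(rownames(df)))
        stop("duplicate gene identifiers in ", path)
    mat <- as.matrix(df)
    if (!is.numeric(mat))
        stop("non-numeric entries in ", path,
            " (is the missing-value token '", missingToken, "'?)")
    miss <- which(is.na(mat), arr.ind = TRUE)
    if (nrow(miss)) {
        if (missingPolicy == "reject") {
            cells <- apply(utils::head(miss, 5L), 1L, function(ij)
                sprintf("(%s, %s)", rownames(mat)[ij[1L]], colnames(mat)[ij[2L]]))
            stop(sprintf("%d missing value(s), e.g. %s; use missingPolicy = 'mean' to impute",
                nrow(miss), paste(cells, collapse = ", ")))
        }
        rm_ <- rowMeans(mat, na.rm = TRUE)
        bad <- which(is.nan(rm_))
        if (length(bad))
            stop("gene(s) with all values missing: ",
                paste(rownames(mat)[bad], collapse = ", "))
        mat[miss] <- rm_[miss[, 1L]]
    }
    .checkMatrix(mat)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [readExpressionMatrix()]: header line of condition ids, one
#' row per gene with its id first. Values are written with 17 significant
#' digits so a read round-trips to the exact binary values.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file.
#' @param delimiter field delimiter (default tab).
#' @export
writeExpressionMatrix <- function(mat, path, delimiter = "\t") {
    mat <- .checkMatrix(mat)
    chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
        dimnames = dimnames(mat))
    df <- data.frame(id = rownames(chr), chr, check.names = FALSE,
        stringsAsFactors = FALSE)
    names(df)[1L] <- ""
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

## result table with gene/condition identifier columns resolved against mat
.resultRecords <- function(x, mat) {
    s <- x@summary
    s$geneIds <- vapply(x@biclusters, function(b)
        paste(rownames(mat)[b@geneIndices], collapse = ";"), "")
    s$conditionIds <- vapply(x@biclusters, function(b)
        paste(colnames(mat)[b@conditionIndices], collapse = ";"), "")
    s[, c("id", "geneIds", "conditionIds", "nGenes", "nConditions",
        "volume", "avgCorr", "corrSd", "fitness", "msr", "geneVariance")]
}

#' Write bicluster results
#'
#' Writes one record per bicluster with the standard report columns —
#' identifiers, number of genes and conditions, volume, average correlation
#' rho(B), its standard deviation sigma(B), fitness, MSR and gene variance —
#' followed by a summary row of column means (id `"average"`). Numeric
#' values are formatted to round-trip at no less than 6 significant digits;
#' the JSON and TSV encodings carry identical values.
#'
#' @param x a [BiclusterSet-class] from [scatterSearch()].
#' @param mat the expression matrix the search was run on (for the gene and
#'   condition identifiers).
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
writeBiclusterResults <- function(x, mat, path, format = c("tsv", "json")) {
    format <- match.arg(format)
    stopifnot(is(x, "BiclusterSet"))
    mat <- .checkMatrix(mat)
    rec <- .resultRecords(x, mat)
    numCols <- c("nGenes", "nConditions", "volume", "avgCorr", "corrSd",
        "fitness", "msr", "geneVariance")
    avg <- as.list(rec[1L, ])
    avg$id <- "average"
    avg$geneIds <- ""
    avg$conditionIds <- ""
    for (cn in numCols)
        avg[[cn]] <- if (nrow(rec)) mean(rec[[cn]]) else NA_real_
    if (format == "tsv") {
        out <- rbind(rec, as.data.frame(avg, stringsAsFactors = FALSE))
        for (cn in numCols)
            out[[cn]] <- sprintf("%.10g", out[[cn]])
        utils::write.table(out, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
    } else {
        payload <- list(
            biclusters = rec,
            average = avg[c("id", numCols)])
        jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
            dataframe = "rows")
    }
    invisible(path)
}
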
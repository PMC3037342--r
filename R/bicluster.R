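#' Construct a Bicluster
#'
#' @param geneIndices integer vector of selected gene (row) indices (1-based,
#'   need not be sorted; duplicates are an error).
#' @param conditionIndices integer vector of selected condition (column)
#'   indices (1-based).
#' @param parentDim integer vector `c(N, L)` giving the parent matrix
#'   dimensions, or the parent matrix itself.
#'
#' @return a [Bicluster-class] object.
#' @examples
#' b <- Bicluster(c(3, 5, 6), c(2, 3), parentDim = c(10, 5))
#' volume(b)  # 6 cells
#' @export
Bicluster <- function(geneIndices = integer(), conditionIndices = integer(),
                      parentDim) {
    if (is.matrix(parentDim))
        parentDim <- dim(parentDim)
    g <- as.integer(geneIndices)
    co <- as.integer(conditionIndices)
    if (anyDuplicated(g) || anyDuplicated(co))
        stop("invalid bicluster: duplicated indices")
    new("Bicluster",
        geneIndices = sort(g),
        conditionIndices = sort(co),
        parentDim = as.integer(parentDim))
}

#' @rdname Bicluster
#' @aliases geneIndices,Bicluster-method
setMethod("geneIndices", "Bicluster", function(x) x@geneIndices)

#' @rdname Bicluster
setMethod("conditionIndices", "Bicluster", function(x) x@conditionIndices)

#' @rdname Bicluster
setMethod("nGenes", "Bicluster", function(x) length(x@geneIndices))

#' @rdname Bicluster
setMethod("nConditions", "Bicluster", function(x) length(x@conditionIndices))

#' @rdname Bicluster
setMethod("volume", "Bicluster",
    function(x) length(x@geneIndices) * length(x@conditionIndices))

setMethod("show", "Bicluster", function(object) {
    cat(sprintf("Bicluster: %d genes x %d conditions (volume %d) of a %d x %d matrix\n",
        nGenes(object), nConditions(object), volume(object),
        object@parentDim[1L], object@parentDim[2L]))
    cat("  genes:      ", .labelRun("g", object@geneIndices), "\n", sep = "")
    cat("  conditions: ", .labelRun("c", object@conditionIndices), "\n", sep = "")
    invisible(object)
})

.labelRun <- function(prefix, idx, max = 12L) {
    if (!length(idx)) return("(none)")
    lab <- paste0(prefix, idx)
    if (length(lab) > max)
        lab <- c(lab[seq_len(max)], sprintf("... (%d total)", length(idx)))
    paste(lab, collapse = " ")
}

#' Binary-string encoding of biclusters
#'
#' A bicluster of an N x L matrix is encoded as a 0/1 vector of length
#' N + L: bit i (i <= N) is 1 iff gene i is selected, bit N + j is 1 iff
#' condition j is selected. For a 10 x 5 matrix, genes \{3, 5, 6\} with
#' conditions \{2, 3\} encode as `0010110000|01100` (the separator is for
#' display only; see [formatBits()]).
#'
#' `encodeBicluster` and `decodeBicluster` are mutually inverse.
#'
#' @param x a [Bicluster-class].
#' @param bits integer vector of 0/1 of length N + L.
#' @param N,L parent matrix dimensions.
#'
#' @return `encodeBicluster`: an integer 0/1 vector of length N + L.
#'   `decodeBicluster`: a [Bicluster-class].
#' @examples
#' b <- Bicluster(c(3, 5, 6), c(2, 3), parentDim = c(10, 5))
#' formatBits(encodeBicluster(b), N = 10)
#' identical(decodeBicluster(encodeBicluster(b), 10, 5), b)
#' @export
encodeBicluster <- function(x) {
    stopifnot(is(x, "Bicluster"))
    validObject(x)
    N <- x@parentDim[1L]
    L <- x@parentDim[2L]
    bits <- integer(N + L)
    bits[x@geneIndices] <- 1L
    bits[N + x@conditionIndices] <- 1L
    bits
}

#' @rdname encodeBicluster
#' @export
decodeBicluster <- function(bits, N, L) {
    bits <- as.integer(bits)
    if (length(bits) != N + L)
        stop(sprintf("dimension mismatch: bit string has length %d, expected N + L = %d",
            length(bits), N + L))
    if (!all(bits %in% c(0L, 1L)))
        stop("bit string must contain only 0 and 1")
    new("Bicluster",
        geneIndices = which(bits[seq_len(N)] == 1L),
        conditionIndices = which(bits[N + seq_len(L)] == 1L),
        parentDim = as.integer(c(N, L)))
}

#' @rdname encodeBicluster
#' @export
formatBits <- function(bits, N) {
    s <- paste(bits, collapse = "")
    if (!missing(N) && N < length(bits))
        s <- paste0(substr(s, 1L, N), "|", substr(s, N + 1L, length(bits)))
    s
}

#' Hamming distance between binary encodings
#'
#' Number of positions at which two equal-length bit strings differ; the
#' diversity measure used when selecting scattered members for the
#' reference set. Also accepts two [Bicluster-class] objects sharing a
#' parent matrix shape (they are encoded first).
#'
#' @param a,b integer 0/1 vectors of equal length, or two `Bicluster`s.
#' @return non-negative integer count.
#' @examples
#' hammingDistance(c(0, 0, 1, 1), c(0, 1, 1, 0))  # 2
#' @export
hammingDistance <- function(a, b) {
    if (is(a, "Bicluster")) a <- encodeBicluster(a)
    if (is(b, "Bicluster")) b <- encodeBicluster(b)
    if (length(a) != length(b))
        stop("dimension mismatch: bit strings differ in length")
    sum(a != b)
}

## Validate an expression matrix: numeric, finite, >= 2 x 2, unique dimnames
## (dimnames are created as g1..gN / c1..cL when absent).
.checkMatrix <- function(mat) {
    if (!is.matrix(mat) || !is.numeric(mat))
        stop("expression matrix must be a numeric matrix")
    if (nrow(mat) < 2L || ncol(mat) < 2L)
        stop("expression matrix must have at least 2 genes and 2 conditions")
    if (!all(is.finite(mat)))
        stop("expression matrix contains non-finite values; apply a missing-value policy first (see readExpressionMatrix)")
    if (is.null(rownames(mat)))
        rownames(mat) <- paste0("g", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("c", seq_len(ncol(mat)))
    if (anyDuplicated(rownames(mat)))
        stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(mat)))
        stop("duplicate condition identifiers")
    mat
}

.checkBiclusterMatrix <- function(x, mat) {
    stopifnot(is(x, "Bicluster"))
    if (!identical(x@parentDim, dim(mat)))
        stop(sprintf("bicluster refers to a %d x %d matrix but a %d x %d matrix was given",
            x@parentDim[1L], x@parentDim[2L], nrow(mat), ncol(mat)))
    invisible(TRUE)
}
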
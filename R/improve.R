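## Gene-pruning core shared by improveBicluster and the search engine.
## C: pairwise correlation matrix of the candidate genes; returns the kept
## positions (into the rows of C), always including position 1.
.improveKeep <- function(C, mode = c("contract", "literal")) {
    mode <- match.arg(mode)
    n <- nrow(C)
    if (n < 2L)
        return(seq_len(n))
    if (mode == "contract") {
        ## keep gene j iff it is strictly positively correlated with every
        ## gene already kept; the first gene anchors the set
        kept <- 1L
        for (j in 2:n) {
            if (all(C[j, kept] > 0))
                kept <- c(kept, j)
        }
        kept
    } else {
        ## faithful trace of the published pseudocode: a sweep over ordered
        ## pairs that adds g_j on the first positive coefficient seen unless
        ## g_j was already rejected, and never removes once added
        inB <- logical(n); inB[1L] <- TRUE
        inR <- logical(n)
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                if (C[i, j] > 0) {
                    if (!inR[j]) inB[j] <- TRUE
                } else {
                    inR[j] <- TRUE
                }
            }
        }
        which(inB)
    }
}

#' Improvement method: strip non-positively-correlated genes
#'
#' The local repair step of the Scatter Search. Starting from the
#' bicluster's first gene, genes are scanned in order and retained only if
#' their pairwise Pearson correlation (over the bicluster's conditions)
#' with the retained set is strictly positive; the condition set is left
#' untouched. Removing the negatively correlated genes shrinks the volume
#' but raises the average correlation — a bicluster of three mutually
#' positively correlated genes plus one anti-correlated gene improves to a
#' 3-gene bicluster with average correlation 1.
#'
#' Two modes are available. `"contract"` (default) enforces the method's
#' output contract: every pair of retained genes has non-negative
#' correlation (gene j is kept iff rho > 0 against each already-kept gene).
#' `"literal"` reproduces the published pseudocode step by step; it can
#' retain a gene that a later comparison finds negatively correlated with
#' an earlier one, and is provided for traceability.
#'
#' Genes constant across the selected conditions have coefficient 0 and are
#' dropped (the retention test is strict). Biclusters with fewer than two
#' genes or two conditions are returned unchanged.
#'
#' @param x a [Bicluster-class].
#' @param mat the parent expression matrix.
#' @param mode `"contract"` or `"literal"`.
#' @return a [Bicluster-class] whose gene set is a subset of the input's
#'   (the first gene is always retained) and whose conditions are unchanged.
#' @examples
#' p <- c(1, 3, 2, 5, 4)
#' m <- rbind(g1 = p, g2 = 2 * p + 1, g3 = 0.5 * p - 2, g4 = -p + 10)
#' colnames(m) <- paste0("c", 1:5)
#' b <- improveBicluster(Bicluster(1:4, 1:5, parentDim = m), m)
#' nGenes(b)             # 3: the anti-correlated g4 is removed
#' avgCorrelation(b, m)  # exactly 1
#' @export
improveBicluster <- function(x, mat, mode = c("contract", "literal")) {
    mode <- match.arg(mode)
    .checkBiclusterMatrix(x, mat)
    if (nGenes(x) < 2L || nConditions(x) < 2L)
        return(x)
    C <- .geneCorrMatrix(mat, x@geneIndices, x@conditionIndices)
    kept <- .improveKeep(C, mode)
    new("Bicluster",
        geneIndices = x@geneIndices[kept],
        conditionIndices = x@conditionIndices,
        parentDim = x@parentDim)
}
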
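#' Construct an implant specification
#'
#' @param nGenes,nConditions size of the implanted bicluster.
#' @param alphaRange range of per-gene scaling factors (strictly positive
#'   so the pattern correlates positively; default `c(0.5, 2)`).
#' @param betaRange range of per-gene shifting offsets (default `c(-2, 2)`).
#' @param noiseSd standard deviation of additive Gaussian noise on
#'   implanted cells; 0 (default) gives exact shifting-and-scaling
#'   patterns with every pairwise gene correlation equal to 1.
#' @return an [ImplantSpec-class] object.
#' @examples
#' ImplantSpec(8, 6)                     # exact pattern
#' ImplantSpec(8, 6, noiseSd = 0.25)     # noisy pattern
#' @export
ImplantSpec <- function(nGenes, nConditions, alphaRange = c(0.5, 2),
                        betaRange = c(-2, 2), noiseSd = 0) {
    new("ImplantSpec",
        nGenes = as.integer(nGenes), nConditions = as.integer(nConditions),
        alphaRange = as.numeric(alphaRange),
        betaRange = as.numeric(betaRange),
        noiseSd = as.numeric(noiseSd))
}

setMethod("show", "ImplantSpec", function(object) {
    cat(sprintf("ImplantSpec: %d x %d, alpha in [%g, %g], beta in [%g, %g], noise sd %g\n",
        object@nGenes, object@nConditions,
        object@alphaRange[1L], object@alphaRange[2L],
        object@betaRange[1L], object@betaRange[2L], object@noiseSd))
    invisible(object)
})

#' Synthetic expression matrix with implanted patterns
#'
#' Generates an N x L matrix of Gaussian background expression and implants
#' the requested shifting-and-scaling biclusters: for each implant a base
#' profile p is drawn from the background distribution and implanted gene i
#' is set to `alpha_i * p + beta_i + noise` over the implant's conditions
#' (alpha uniform in `alphaRange`, beta uniform in `betaRange`). Implants
#' occupy disjoint contiguous row and column blocks, placed in order from
#' the top-left corner, so the ground truth is unambiguous.
#'
#' @param N,L matrix dimensions (genes x conditions).
#' @param implants list of [ImplantSpec-class] objects; they must fit into
#'   disjoint blocks of the matrix.
#' @param backgroundMean,backgroundSd parameters of the Gaussian background
#'   (defaults 0 and 1).
#' @param seed optional integer seed; generation is deterministic per seed.
#' @return a list with elements `matrix` (the N x L expression matrix with
#'   gene ids `g1..gN` and condition ids `c1..cL`) and `truth` (list of
#'   [Bicluster-class] ground-truth positions, one per implant).
#' @examples
#' sim <- makeSyntheticMatrix(50, 20, list(ImplantSpec(8, 6)), seed = 1)
#' avgCorrelation(sim$truth[[1]], sim$matrix)  # exactly 1 (zero noise)
#' @export
makeSyntheticMatrix <- function(N, L, implants = list(),
                                backgroundMean = 0, backgroundSd = 1,
                                seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    N <- as.integer(N); L <- as.integer(L)
    stopifnot(N >= 2L, L >= 2L)
    for (sp in implants) {
        stopifnot(is(sp, "ImplantSpec"))
        validObject(sp)
    }
    if (length(implants)) {
        if (sum(vapply(implants, slot, 0L, "nGenes")) > N ||
            sum(vapply(implants, slot, 0L, "nConditions")) > L)
            stop("implants do not fit inside the matrix dimensions")
    }
    mat <- matrix(stats::rnorm(N * L, backgroundMean, backgroundSd), N, L,
        dimnames = list(paste0("g", seq_len(N)), paste0("c", seq_len(L))))
    nextG <- 1L
    nextC <- 1L
    truth <- vector("list", length(implants))
    for (k in seq_along(implants)) {
        sp <- implants[[k]]
        gsel <- seq.int(nextG, length.out = sp@nGenes)
        csel <- seq.int(nextC, length.out = sp@nConditions)
        nextG <- nextG + sp@nGenes
        nextC <- nextC + sp@nConditions
        p <- stats::rnorm(sp@nConditions, backgroundMean, backgroundSd)
        alpha <- stats::runif(sp@nGenes, sp@alphaRange[1L], sp@alphaRange[2L])
        beta <- stats::runif(sp@nGenes, sp@betaRange[1L], sp@betaRange[2L])
        block <- outer(alpha, p) + beta
        if (sp@noiseSd > 0)
            block <- block + matrix(stats::rnorm(length(block), 0, sp@noiseSd),
                nrow(block), ncol(block))
        mat[gsel, csel] <- block
        truth[[k]] <- Bicluster(gsel, csel, parentDim = c(N, L))
    }
    list(matrix = mat, truth = truth)
}

#' Cell-level Jaccard overlap between two biclusters
#'
#' Treats each bicluster as its set of (gene, condition) cells and returns
#' `|intersection| / |union|`, the recovery score used to judge whether a
#' found bicluster matches an implanted ground truth.
#'
#' @param found,truth two [Bicluster-class] objects on the same parent
#'   matrix shape.
#' @return overlap in \[0, 1\]; 1 for identical biclusters, 0 for disjoint
#'   ones (and for two empty biclusters, by convention).
#' @export
jaccardRecovery <- function(found, truth) {
    if (!identical(found@parentDim, truth@parentDim))
        stop("biclusters refer to different parent matrices")
    inter <- length(intersect(found@geneIndices, truth@geneIndices)) *
        length(intersect(found@conditionIndices, truth@conditionIndices))
    uni <- volume(found) + volume(truth) - inter
    if (uni == 0L) return(0)
    inter / uni
}

#' Write the ground truth of a synthetic matrix
#'
#' Sidecar to [writeExpressionMatrix()]: one row per implant with the
#' implant id and the semicolon-separated gene and condition identifiers of
#' the true bicluster.
#'
#' @param truth list of [Bicluster-class] objects (the `truth` element of
#'   [makeSyntheticMatrix()]).
#' @param mat the synthetic matrix (for its identifiers).
#' @param path output file.
#' @param delimiter column delimiter (default tab).
#' @export
writeImplantTruth <- function(truth, mat, path, delimiter = "\t") {
    df <- data.frame(
        implant = paste0("implant", seq_along(truth)),
        genes = vapply(truth, function(b)
            paste(rownames(mat)[b@geneIndices], collapse = ";"), ""),
        conditions = vapply(truth, function(b)
            paste(colnames(mat)[b@conditionIndices], collapse = ";"), ""),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
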
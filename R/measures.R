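#' Pearson correlation between two expression vectors
#'
#' Computed from the population-moment definition
#' `rho(X, Y) = sum((x - mean(x)) * (y - mean(y))) / (n * sd(x) * sd(y))`
#' with divide-by-n standard deviations. Because rho is a ratio, the sample
#' (n - 1) form gives the same value. Two genes in a shifting-and-scaling
#' relation `y = alpha * x + beta` have rho = 1 when alpha > 0 and
#' rho = -1 when alpha < 0.
#'
#' A vector that is constant (zero variance) is treated as uncorrelated:
#' the coefficient is defined as 0. This keeps the measure total; the
#' improvement method then drops such genes as non-positive.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation coefficient in \[-1, 1\].
#' @examples
#' pearsonCorr(c(1, 2, 3), c(3, 5, 7))   #  1, y = 2x + 1
#' pearsonCorr(c(1, 2, 3), c(6, 4, 2))   # -1
#' pearsonCorr(c(1, 2, 3), c(1, 3, 2))   #  0.5
#' @export
pearsonCorr <- function(x, y) {
    if (length(x) != length(y))
        stop("dimension mismatch: vectors differ in length")
    n <- length(x)
    if (n < 2L)
        stop("correlation requires vectors of length >= 2")
    dx <- x - mean(x)
    dy <- y - mean(y)
    sx <- sqrt(mean(dx^2))
    sy <- sqrt(mean(dy^2))
    if (sx == 0 || sy == 0)
        return(0)
    r <- sum(dx * dy) / (n * sx * sy)
    ## clamp rounding excursions beyond [-1, 1]
    max(-1, min(1, r))
}

## Pairwise gene correlation matrix over the selected conditions.
## genes x genes; NA from zero-variance genes mapped to 0, diagonal to 1.
.geneCorrMatrix <- function(mat, genes, conds) {
    sub <- mat[genes, conds, drop = FALSE]
    C <- suppressWarnings(stats::cor(t(sub)))
    C[is.na(C)] <- 0
    diag(C) <- 1
    C
}

## mean and population SD of the upper-triangle coefficients
.corrSummary <- function(C) {
    v <- C[upper.tri(C)]
    m <- mean(v)
    list(avgCorr = m, corrSd = sqrt(mean((v - m)^2)))
}

.fitnessFromScores <- function(avgCorr, corrSd, nG, nC, M1, M2) {
    if (nG < 2L || nC < 2L)
        return(Inf)
    (1 - avgCorr) + corrSd + M1 / nG + M2 / nC
}

#' Average pairwise gene correlation of a bicluster
#'
#' The mean of the `choose(nG, 2)` pairwise Pearson coefficients
#' `rho(g_i, g_j)`, i < j, computed over the bicluster's selected
#' conditions only. A bicluster whose genes are all positive affine
#' transforms of one base profile (a perfect shifting-and-scaling pattern)
#' has average correlation exactly 1.
#'
#' `corrSD` is the population standard deviation of the same coefficients;
#' it is 0 when every pair is equally correlated (including the 2-gene
#' case, which has a single coefficient).
#'
#' @param x a [Bicluster-class] with at least 2 genes and 2 conditions.
#' @param mat the parent expression matrix.
#' @return `avgCorrelation`: the mean coefficient in \[-1, 1\];
#'   `corrSD`: its population standard deviation (>= 0). Both are `NA`
#'   for degenerate biclusters (fewer than 2 genes or conditions); the
#'   fitness maps that case to `Inf`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(3, 5, 7, 9))
#' colnames(m) <- paste0("c", 1:4)
#' avgCorrelation(Bicluster(1:3, 1:4, parentDim = m), m)  # exactly 1
#' @export
avgCorrelation <- function(x, mat) {
    .checkBiclusterMatrix(x, mat)
    if (nGenes(x) < 2L || nConditions(x) < 2L)
        return(NA_real_)
    C <- .geneCorrMatrix(mat, x@geneIndices, x@conditionIndices)
    .corrSummary(C)$avgCorr
}

#' @rdname avgCorrelation
#' @export
corrSD <- function(x, mat) {
    .checkBiclusterMatrix(x, mat)
    if (nGenes(x) < 2L || nConditions(x) < 2L)
        return(NA_real_)
    C <- .geneCorrMatrix(mat, x@geneIndices, x@conditionIndices)
    .corrSummary(C)$corrSd
}

#' Composite fitness of a bicluster
#'
#' `f(B) = (1 - rho(B)) + sigma_rho + M1 / nGenes + M2 / nConditions`,
#' where rho(B) is the average pairwise gene correlation and sigma_rho the
#' population standard deviation of the pairwise coefficients. Lower is
#' better: 0 is approached by large biclusters whose genes are perfectly
#' and homogeneously positively correlated. The penalty weights M1 and M2
#' steer the search toward larger gene and condition sets; degenerate
#' biclusters (fewer than 2 genes or 2 conditions) receive `Inf` so the
#' evolutionary loop never selects them.
#'
#' @inheritParams avgCorrelation
#' @param M1,M2 non-negative volume penalty weights.
#' @return the fitness value (>= 0, possibly `Inf`).
#' @examples
#' m <- outer(1:10, 1:5) + 0.5  # rank-1: all rows perfectly correlated
#' rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("c", 1:5)
#' biclusterFitness(Bicluster(1:10, 1:5, parentDim = m), m, M1 = 1, M2 = 1)
#' # 0 + 0 + 1/10 + 1/5 = 0.3
#' @export
biclusterFitness <- function(x, mat, M1 = 1, M2 = 1) {
    .checkBiclusterMatrix(x, mat)
    nG <- nGenes(x)
    nC <- nConditions(x)
    if (nG < 2L || nC < 2L)
        return(Inf)
    C <- .geneCorrMatrix(mat, x@geneIndices, x@conditionIndices)
    s <- .corrSummary(C)
    .fitnessFromScores(s$avgCorr, s$corrSd, nG, nC, M1, M2)
}

#' Mean squared residue of a bicluster
#'
#' The Cheng & Church residue score: the mean over the bicluster's cells of
#' `(a_ij - a_iJ - a_Ij + a_IJ)^2` where `a_iJ`, `a_Ij` and `a_IJ` are the
#' row, column and overall means of the submatrix. It is 0 for constant and
#' for pure shifting biclusters, but grows with the spread of scaling
#' factors even when all genes are perfectly correlated — the weakness of
#' MSR-driven searches that a correlation fitness avoids.
#'
#' @inheritParams avgCorrelation
#' @return mean squared residue (>= 0); `NA` for an empty bicluster.
#' @examples
#' m <- rbind(c(1, 2), c(3, 5))
#' rownames(m) <- c("g1", "g2"); colnames(m) <- c("c1", "c2")
#' biclusterMSR(Bicluster(1:2, 1:2, parentDim = m), m)  # 0.0625
#' @export
biclusterMSR <- function(x, mat) {
    .checkBiclusterMatrix(x, mat)
    if (nGenes(x) < 1L || nConditions(x) < 1L)
        return(NA_real_)
    sub <- mat[x@geneIndices, x@conditionIndices, drop = FALSE]
    res <- sweep(sweep(sub, 1L, rowMeans(sub)), 2L, colMeans(sub)) + mean(sub)
    mean(res^2)
}

#' Gene (row) variance of a bicluster
#'
#' The mean over cells of the squared deviation from the cell's gene mean
#' across the selected conditions. It measures how far expression levels
#' move — a scaling pattern with widely spread scaling factors has large
#' gene variance while keeping average correlation 1, which is exactly the
#' regime in which MSR-based searches discard good biclusters.
#'
#' @inheritParams avgCorrelation
#' @return mean squared deviation from gene means (>= 0); `NA` when empty.
#' @examples
#' m <- rbind(g1 = c(1, 3), g2 = c(2, 6)); colnames(m) <- c("c1", "c2")
#' geneVariance(Bicluster(1:2, 1:2, parentDim = m), m)  # 2.5
#' @export
geneVariance <- function(x, mat) {
    .checkBiclusterMatrix(x, mat)
    if (nGenes(x) < 1L || nConditions(x) < 2L)
        return(NA_real_)
    sub <- mat[x@geneIndices, x@conditionIndices, drop = FALSE]
    mean(sweep(sub, 1L, rowMeans(sub))^2)
}

#' Score a bicluster on all quality measures
#'
#' Computes the full measure bundle in one pass: average pairwise gene
#' correlation, its population standard deviation, the composite fitness,
#' the mean squared residue, the gene variance and the volume.
#'
#' @inheritParams biclusterFitness
#' @return a [BiclusterScore-class] object.
#' @examples
#' m <- outer(1:6, 1:4) + 1
#' rownames(m) <- paste0("g", 1:6); colnames(m) <- paste0("c", 1:4)
#' scoreBicluster(Bicluster(1:6, 1:4, parentDim = m), m)
#' @export
scoreBicluster <- function(x, mat, M1 = 1, M2 = 1) {
    .checkBiclusterMatrix(x, mat)
    nG <- nGenes(x)
    nC <- nConditions(x)
    if (nG < 2L || nC < 2L) {
        return(new("BiclusterScore", avgCorr = NA_real_, corrSd = NA_real_,
            fitness = Inf, msr = NA_real_, geneVariance = NA_real_,
            volume = as.integer(nG * nC), M1 = M1, M2 = M2))
    }
    C <- .geneCorrMatrix(mat, x@geneIndices, x@conditionIndices)
    s <- .corrSummary(C)
    new("BiclusterScore",
        avgCorr = s$avgCorr,
        corrSd = s$corrSd,
        fitness = .fitnessFromScores(s$avgCorr, s$corrSd, nG, nC, M1, M2),
        msr = biclusterMSR(x, mat),
        geneVariance = geneVariance(x, mat),
        volume = as.integer(nG * nC),
        M1 = M1, M2 = M2)
}

setMethod("show", "BiclusterScore", function(object) {
    cat("BiclusterScore\n")
    cat(sprintf("  avgCorr (rho):   %.4f\n", object@avgCorr))
    cat(sprintf("  corrSd (sigma):  %.4f\n", object@corrSd))
    cat(sprintf("  fitness:         %.4f  (M1 = %g, M2 = %g)\n",
        object@fitness, object@M1, object@M2))
    cat(sprintf("  MSR:             %.4f\n", object@msr))
    cat(sprintf("  gene variance:   %.4f\n", object@geneVariance))
    cat(sprintf("  volume:          %d\n", object@volume))
    invisible(object)
})
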
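#' @import methods
NULL

#' Bicluster: a gene/condition submatrix selection
#'
#' A bicluster is a subset of gene (row) indices and condition (column)
#' indices of a parent expression matrix. It is equivalent to a binary
#' string of length N + L where the first N bits select genes and the last
#' L bits select conditions (see [encodeBicluster()]).
#'
#' Empty gene or condition sets are representable: the combination operator
#' of the search can produce them, and they are handled by assigning the
#' worst possible fitness rather than by raising an error.
#'
#' @slot geneIndices sorted integer vector of selected gene (row) indices,
#'   1-based.
#' @slot conditionIndices sorted integer vector of selected condition
#'   (column) indices, 1-based.
#' @slot parentDim integer vector `c(N, L)`: dimensions of the parent
#'   expression matrix the indices refer to.
#'
#' @seealso [Bicluster()], [encodeBicluster()], [decodeBicluster()],
#'   [scoreBicluster()]
#' @export
setClass("Bicluster",
    representation(
        geneIndices = "integer",
        conditionIndices = "integer",
        parentDim = "integer"
    )
)

setValidity("Bicluster", function(object) {
    msg <- character()
    d <- object@parentDim
    if (length(d) != 2L || anyNA(d) || any(d < 1L))
        msg <- c(msg, "parentDim must be two positive integers c(N, L)")
    g <- object@geneIndices
    co <- object@conditionIndices
    if (anyNA(g) || anyNA(co))
        msg <- c(msg, "indices must not contain NA")
    if (is.unsorted(g, strictly = TRUE) && length(g) > 1L)
        msg <- c(msg, "geneIndices must be strictly increasing")
    if (is.unsorted(co, strictly = TRUE) && length(co) > 1L)
        msg <- c(msg, "conditionIndices must be strictly increasing")
    if (length(d) == 2L && !anyNA(d)) {
        if (length(g) && (min(g) < 1L || max(g) > d[1L]))
            msg <- c(msg, sprintf("geneIndices out of range [1, %d]", d[1L]))
        if (length(co) && (min(co) < 1L || max(co) > d[2L]))
            msg <- c(msg, sprintf("conditionIndices out of range [1, %d]", d[2L]))
    }
    if (length(msg)) msg else TRUE
})

#' Quality measures of one bicluster
#'
#' Bundles the scalar quality measures of a bicluster: the average pairwise
#' Pearson correlation among its genes (rho), the population standard
#' deviation of those pairwise coefficients (sigma), the composite fitness
#' (lower is better), the mean squared residue, the gene (row) variance and
#' the volume (number of cells).
#'
#' @slot avgCorr average pairwise gene correlation, in \[-1, 1\].
#' @slot corrSd population standard deviation of the pairwise coefficients.
#' @slot fitness `(1 - avgCorr) + corrSd + M1/nG + M2/nC`; `Inf` for
#'   degenerate biclusters (fewer than 2 genes or 2 conditions).
#' @slot msr mean squared residue (Cheng & Church residue, mean of squares).
#' @slot geneVariance mean squared deviation of cells from their gene means.
#' @slot volume number of cells, `nGenes * nConditions`.
#' @slot M1,M2 the penalty factors the fitness was computed with.
#'
#' @seealso [scoreBicluster()]
#' @export
setClass("BiclusterScore",
    representation(
        avgCorr = "numeric",
        corrSd = "numeric",
        fitness = "numeric",
        msr = "numeric",
        geneVariance = "numeric",
        volume = "integer",
        M1 = "numeric",
        M2 = "numeric"
    )
)

#' Tuning parameters of the biclustering Scatter Search
#'
#' Holds every tunable of the search. Defaults follow the published study
#' settings: 20 outer iterations, reference set of size 10, initial
#' population of 200 solutions, 100 biclusters per run, and volume penalties
#' M1 = M2 = 1 (use 10 to favour larger biclusters).
#'
#' @slot numBiclusters number of independent Scatter Search restarts, each
#'   contributing its best bicluster to the result set (numBi).
#' @slot numIterations outer iterations per restart: each runs the
#'   combination/update loop to stability and then rebuilds the reference
#'   set (numIter).
#' @slot refSetSize even size S of the reference set (S/2 quality half,
#'   S/2 diversity half).
#' @slot populationSize size of the diversification-generated population.
#' @slot M1,M2 non-negative penalty weights on 1/nGenes and 1/nConditions in
#'   the fitness; larger values push the search toward larger biclusters.
#' @slot hMaxDivisor the diversification stride h ranges over
#'   `1 <= h < n / hMaxDivisor` (default 5) where n = N + L.
#' @slot improveMode `"contract"` (default; every retained gene pair is
#'   positively correlated) or `"literal"` (trace of the published
#'   pseudocode) — see [improveBicluster()].
#'
#' @seealso [ScatterSearchParam()], [scatterSearch()]
#' @export
setClass("ScatterSearchParam",
    representation(
        numBiclusters = "integer",
        numIterations = "integer",
        refSetSize = "integer",
        populationSize = "integer",
        M1 = "numeric",
        M2 = "numeric",
        hMaxDivisor = "integer",
        improveMode = "character"
    )
)

setValidity("ScatterSearchParam", function(object) {
    msg <- character()
    if (object@numBiclusters < 1L)
        msg <- c(msg, "numBiclusters must be >= 1")
    if (object@numIterations < 0L)
        msg <- c(msg, "numIterations must be >= 0")
    S <- object@refSetSize
    if (S < 2L || S %% 2L != 0L)
        msg <- c(msg, "refSetSize must be an even integer >= 2")
    if (object@populationSize <= S)
        msg <- c(msg, "populationSize must exceed refSetSize")
    if (object@M1 < 0 || object@M2 < 0)
        msg <- c(msg, "M1 and M2 must be non-negative")
    if (object@hMaxDivisor < 1L)
        msg <- c(msg, "hMaxDivisor must be >= 1")
    if (!object@improveMode %in% c("contract", "literal"))
        msg <- c(msg, "improveMode must be 'contract' or 'literal'")
    if (length(msg)) msg else TRUE
})

#' A set of biclusters found by the Scatter Search
#'
#' Container for the result of [scatterSearch()]: the biclusters themselves
#' plus a per-bicluster table of quality statistics (genes, conditions,
#' volume, average correlation, its standard deviation, fitness, mean
#' squared residue and gene variance).
#'
#' @slot biclusters list of [Bicluster-class] objects.
#' @slot summary `data.frame`, one row per bicluster with columns `id`,
#'   `nGenes`, `nConditions`, `volume`, `avgCorr`, `corrSd`, `fitness`,
#'   `msr`, `geneVariance`.
#' @slot param the [ScatterSearchParam-class] the search was run with.
#'
#' @seealso [scatterSearch()], [writeBiclusterResults()]
#' @export
setClass("BiclusterSet",
    representation(
        biclusters = "list",
        summary = "data.frame",
        param = "ScatterSearchParam"
    )
)

setValidity("BiclusterSet", function(object) {
    if (length(object@biclusters) != nrow(object@summary))
        return("summary must have one row per bicluster")
    if (!all(vapply(object@biclusters, is, logical(1), "Bicluster")))
        return("biclusters must all be Bicluster objects")
    TRUE
})

#' Specification of one implanted bicluster pattern
#'
#' Describes a shifting-and-scaling pattern to implant into a synthetic
#' expression matrix: every implanted gene is `alpha_i * p + beta_i + noise`
#' for one base profile p, with per-gene `alpha_i` drawn from `alphaRange`
#' (strictly positive, so all pairwise correlations are +1 at zero noise)
#' and `beta_i` from `betaRange`.
#'
#' @slot nGenes,nConditions size of the implanted block.
#' @slot alphaRange length-2 positive numeric: range of scaling factors.
#' @slot betaRange length-2 numeric: range of shifting offsets.
#' @slot noiseSd standard deviation of the additive Gaussian noise; 0 gives
#'   exact patterns.
#'
#' @seealso [ImplantSpec()], [makeSyntheticMatrix()]
#' @export
setClass("ImplantSpec",
    representation(
        nGenes = "integer",
        nConditions = "integer",
        alphaRange = "numeric",
        betaRange = "numeric",
        noiseSd = "numeric"
    )
)

setValidity("ImplantSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@nConditions < 1L)
        msg <- c(msg, "implant dimensions must be positive")
    a <- object@alphaRange
    if (length(a) != 2L || any(a <= 0) || a[1L] > a[2L])
        msg <- c(msg, "alphaRange must be a strictly positive interval")
    b <- object@betaRange
    if (length(b) != 2L || b[1L] > b[2L])
        msg <- c(msg, "betaRange must be a valid interval")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})
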
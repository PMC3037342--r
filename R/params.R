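#' Construct search parameters
#'
#' @param numBiclusters number of independent restarts / biclusters to
#'   report (default 100).
#' @param numIterations outer iterations per restart (default 20).
#' @param refSetSize even reference-set size S (default 10).
#' @param populationSize diversification population size (default 200).
#' @param M1,M2 volume penalty weights (default 1; use 10 for larger
#'   biclusters).
#' @param hMaxDivisor bound divisor for the diversification stride
#'   (h < n / hMaxDivisor, default 5).
#' @param improveMode `"contract"` (default) or `"literal"`; see
#'   [improveBicluster()].
#'
#' @return a [ScatterSearchParam-class] object.
#' @examples
#' ScatterSearchParam(numBiclusters = 5, M1 = 10, M2 = 10)
#' @export
ScatterSearchParam <- function(numBiclusters = 100L, numIterations = 20L,
                               refSetSize = 10L, populationSize = 200L,
                               M1 = 1, M2 = 1, hMaxDivisor = 5L,
                               improveMode = c("contract", "literal")) {
    improveMode <- match.arg(improveMode)
    new("ScatterSearchParam",
        numBiclusters = as.integer(numBiclusters),
        numIterations = as.integer(numIterations),
        refSetSize = as.integer(refSetSize),
        populationSize = as.integer(populationSize),
        M1 = as.numeric(M1), M2 = as.numeric(M2),
        hMaxDivisor = as.integer(hMaxDivisor),
        improveMode = improveMode)
}

setMethod("show", "ScatterSearchParam", function(object) {
    cat("ScatterSearchParam\n")
    cat(sprintf("  numBiclusters:  %d\n", object@numBiclusters))
    cat(sprintf("  numIterations:  %d\n", object@numIterations))
    cat(sprintf("  refSetSize:     %d\n", object@refSetSize))
    cat(sprintf("  populationSize: %d\n", object@populationSize))
    cat(sprintf("  M1, M2:         %g, %g\n", object@M1, object@M2))
    cat(sprintf("  hMaxDivisor:    %d\n", object@hMaxDivisor))
    cat(sprintf("  improveMode:    %s\n", object@improveMode))
    invisible(object)
})
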
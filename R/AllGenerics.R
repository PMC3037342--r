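#' @rdname Bicluster
#' @param x a `Bicluster` (or `BiclusterSet` where documented).
#' @export
setGeneric("geneIndices", function(x) standardGeneric("geneIndices"))

#' @rdname Bicluster
#' @export
setGeneric("conditionIndices", function(x) standardGeneric("conditionIndices"))

#' @rdname Bicluster
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname Bicluster
#' @export
setGeneric("nConditions", function(x) standardGeneric("nConditions"))

#' @rdname Bicluster
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))
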
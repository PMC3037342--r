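#' @describeIn BiclusterSet number of biclusters in the set.
#' @param x a `BiclusterSet`.
#' @export
setMethod("length", "BiclusterSet", function(x) length(x@biclusters))

#' @describeIn BiclusterSet extract one bicluster.
#' @param i index.
#' @param j,... unused.
#' @export
setMethod("[[", "BiclusterSet", function(x, i, j, ...) x@biclusters[[i]])

#' @describeIn BiclusterSet the per-bicluster statistics table.
#' @param row.names,optional passed on conventionally, unused.
#' @export
setMethod("as.data.frame", "BiclusterSet",
    function(x, row.names = NULL, optional = FALSE, ...) x@summary)

setMethod("show", "BiclusterSet", function(object) {
    n <- length(object)
    cat(sprintf("BiclusterSet with %d bicluster%s\n", n, if (n == 1) "" else "s"))
    if (n > 0) {
        s <- object@summary
        cat(sprintf("  mean volume %.1f, mean avgCorr %.3f, best fitness %.4f\n",
            mean(s$volume), mean(s$avgCorr, na.rm = TRUE), min(s$fitness)))
        print(utils::head(s, 5L), row.names = FALSE)
        if (n > 5L) cat(sprintf("  ... and %d more\n", n - 5L))
    }
    invisible(object)
})
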
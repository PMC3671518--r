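#' Accessors for ContigCountSet
#'
#' `libTotals()` returns the named per-library totals of uniquely mapped
#' reads; `contigLengths()` returns the named per-contig lengths in bp.
#'
#' @param x a \linkS4class{ContigCountSet}.
#' @return a named numeric vector.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 9L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("BL", "BK")))
#' ccs <- ContigCountSet(m, lengths = c(400, 1200))
#' contigLengths(ccs)
#' @export
setGeneric("libTotals", function(x) standardGeneric("libTotals"))

#' @rdname libTotals
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname libTotals
#' @export
setMethod("libTotals", "ContigCountSet", function(x) {
    tot <- SummarizedExperiment::colData(x)$libTotal
    names(tot) <- colnames(x)
    tot
})

#' @rdname libTotals
#' @export
setMethod("contigLengths", "ContigCountSet", function(x) {
    len <- SummarizedExperiment::rowData(x)$length
    names(len) <- rownames(x)
    len
})
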
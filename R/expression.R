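#' RPKM quantification
#'
#' Reads per kilobase of contig per million mapped reads:
#' \eqn{RPKM = 10^9 C / (N L)} with `C` the contig's uniquely mapped read
#' count, `N` the library total and `L` the contig length in bp.
#'
#' @param counts a \linkS4class{ContigCountSet}, or a contigs x libraries
#'   integer matrix.
#' @param lengths per-contig lengths in bp (ignored for a `ContigCountSet`).
#' @param libTotals per-library totals (ignored for a `ContigCountSet`).
#' @return numeric matrix of RPKM values with the same dimnames as the
#'   counts.
#' @examples
#' computeRPKM(matrix(1000L, 1, 1, dimnames = list("c1", "BL")),
#'             lengths = 1000, libTotals = 1e6)   # 1000
#' @export
setGeneric("computeRPKM",
    function(counts, lengths, libTotals) standardGeneric("computeRPKM"),
    signature = "counts")

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", "ContigCountSet", function(counts, lengths,
                                                    libTotals) {
    totFun <- methods::getMethod("libTotals", "ContigCountSet")
    computeRPKM(SummarizedExperiment::assay(counts, "counts"),
                contigLengths(counts), totFun(counts))
})

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", "matrix", function(counts, lengths, libTotals) {
    if (length(lengths) != nrow(counts))
        stop("one length per contig is required")
    if (any(is.na(lengths)) || any(lengths <= 0))
        stop("contig lengths must be positive")
    if (length(libTotals) != ncol(counts) || any(libTotals <= 0))
        stop("one positive total per library is required")
    1e9 * sweep(sweep(counts, 2, libTotals, "/"), 1, lengths, "/")
})

#' Call differentially expressed contigs between two libraries
#'
#' Runs the Audic-Claverie test on every contig for one pairwise library
#' comparison, adjusts the p-values (Benjamini-Hochberg by default), and
#' applies the dual significance criterion: adjusted q-value below
#' `qThreshold` AND an RPKM fold change of at least `fcThreshold` in either
#' direction (inclusive thresholds). The fold change used for the criterion
#' adds one pseudo-read to both counts before forming the RPKM ratio so
#' presence/absence contigs get a finite, conservative ratio; the reported
#' RPKM columns are unmodified. Sample one of `pair` is the reference:
#' `direction == "up"` means higher in sample two.
#'
#' @param counts a \linkS4class{ContigCountSet}.
#' @param pair character vector of two library names,
#'   `c(reference, treatment)`.
#' @param qThreshold significance threshold on the adjusted q-value
#'   (default 1e-3).
#' @param fcThreshold fold-change threshold >= 1 (default 2; "at least
#'   2-fold" is inclusive).
#' @param adjust multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return a [S4Vectors::DataFrame] with one row per contig: `x`, `y`
#'   (counts in samples one/two), `rpkm1`, `rpkm2`, `foldChange`
#'   (stabilised, sample two / sample one), `pointProb`, `pValue`, `qValue`,
#'   `direction` (`up`/`down`/`none`) and `significant`. The comparison
#'   label (`"<ref>_vs_<other>"`) and thresholds are in `metadata()`.
#' @examples
#' sim <- simulateStudy(SimParams(nContigs = 200, libraryDepths =
#'     c(BL = 5e4, BK = 5e4), deFold = 8, seed = 3))
#' calls <- callDEGs(sim$counts, c("BL", "BK"))
#' table(calls$direction[calls$significant])
#' @export
callDEGs <- function(counts, pair, qThreshold = 1e-3, fcThreshold = 2,
                     adjust = "BH") {
    stopifnot(is(counts, "ContigCountSet"))
    if (length(pair) != 2L || !all(pair %in% colnames(counts)))
        stop("'pair' must name two libraries present in the count table")
    if (qThreshold <= 0 || fcThreshold < 1)
        stop("thresholds must satisfy qThreshold > 0 and fcThreshold >= 1")
    tot <- libTotals(counts)
    N1 <- tot[[pair[1L]]]; N2 <- tot[[pair[2L]]]
    x <- SummarizedExperiment::assay(counts, "counts")[, pair[1L]]
    y <- SummarizedExperiment::assay(counts, "counts")[, pair[2L]]
    rpkm <- computeRPKM(counts)[, pair, drop = FALSE]
    pp <- acPointProb(x, y, N1, N2)
    p <- acPValue(x, y, N1, N2)
    q <- if (identical(adjust, "BH")) bhAdjust(p) else
        stats::p.adjust(p, method = adjust)
    # pseudo-read stabilised RPKM ratio; contig length cancels
    fc <- ((y + 1) / N2) / ((x + 1) / N1)
    sig <- q < qThreshold & (fc >= fcThreshold | fc <= 1 / fcThreshold)
    dir <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
    res <- S4Vectors::DataFrame(
        x = x, y = y,
        rpkm1 = rpkm[, 1L], rpkm2 = rpkm[, 2L],
        foldChange = fc, pointProb = pp, pValue = p, qValue = q,
        direction = dir, significant = sig,
        row.names = rownames(counts))
    S4Vectors::metadata(res) <- list(
        label = paste0(pair[1L], "_vs_", pair[2L]),
        reference = pair[1L], treatment = pair[2L],
        N1 = N1, N2 = N2,
        qThreshold = qThreshold, fcThreshold = fcThreshold,
        adjust = adjust)
    res
}

#' Cross-comparison consistency (Venn) of DEG calls
#'
#' Intersects the significant up- and down-regulated contig sets of two
#' pairwise comparisons sharing the same reference sample, as in a Venn
#' diagram of shared DEGs.
#'
#' @param callsA,callsB `DataFrame`s from [callDEGs()] with a common
#'   reference sample.
#' @return a list of class `"VennSummary"`: per-comparison up/down counts,
#'   `consistentUp` / `consistentDown` id vectors, their sizes, and
#'   `totalConsistent`.
#' @examples
#' sim <- simulateStudy(SimParams(nContigs = 300, deFold = 8, seed = 5))
#' a <- callDEGs(sim$counts, c("BL", "BK"))
#' b <- callDEGs(sim$counts, c("BL", "BS"))
#' consistentDEGs(a, b)$totalConsistent
#' @export
consistentDEGs <- function(callsA, callsB) {
    refA <- S4Vectors::metadata(callsA)$reference
    refB <- S4Vectors::metadata(callsB)$reference
    if (is.null(refA) || is.null(refB) || !identical(refA, refB))
        stop("both call sets must share the same reference sample")
    up <- function(z) rownames(z)[z$significant & z$direction == "up"]
    dn <- function(z) rownames(z)[z$significant & z$direction == "down"]
    cu <- intersect(up(callsA), up(callsB))
    cd <- intersect(dn(callsA), dn(callsB))
    out <- list(
        comparisons = c(S4Vectors::metadata(callsA)$label,
                        S4Vectors::metadata(callsB)$label),
        upCounts = c(length(up(callsA)), length(up(callsB))),
        downCounts = c(length(dn(callsA)), length(dn(callsB))),
        consistentUp = cu, consistentDown = cd,
        nConsistentUp = length(cu), nConsistentDown = length(cd),
        totalConsistent = length(cu) + length(cd))
    class(out) <- "VennSummary"
    out
}

#' @export
print.VennSummary <- function(x, ...) {
    cat("Consistency of", x$comparisons[1], "and", x$comparisons[2], "\n")
    cat(sprintf("  up:   %d & %d -> %d shared\n",
                x$upCounts[1], x$upCounts[2], x$nConsistentUp))
    cat(sprintf("  down: %d & %d -> %d shared\n",
                x$downCounts[1], x$downCounts[2], x$nConsistentDown))
    cat("  total consistent DEGs:", x$totalConsistent, "\n")
    invisible(x)
}

#' Per-library mapping-rate summary
#'
#' Computes the percentage of clean (quality-filtered) reads that mapped
#' uniquely back to the assembly, per library.
#'
#' @param stats data frame with columns `sample`, `totalReads`,
#'   `cleanReads`, `mappedReads` (all read counts;
#'   `mapped <= clean <= total` and `clean > 0`).
#' @return the input with an added `mappedPerClean` column, the mapping
#'   rate in percent rounded to one decimal.
#' @examples
#' mappingSummary(data.frame(sample = "BL", totalReads = 41232601,
#'     cleanReads = 40731588, mappedReads = 35593595))$mappedPerClean
#' @export
mappingSummary <- function(stats) {
    need <- c("sample", "totalReads", "cleanReads", "mappedReads")
    if (!all(need %in% names(stats)))
        stop("'stats' needs columns: ", paste(need, collapse = ", "))
    if (any(stats$cleanReads <= 0))
        stop("cleanReads must be positive")
    if (any(stats$mappedReads > stats$cleanReads) ||
        any(stats$cleanReads > stats$totalReads))
        stop("expected mappedReads <= cleanReads <= totalReads")
    stats$mappedPerClean <- round(100 * stats$mappedReads / stats$cleanReads,
                                  1)
    stats
}
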
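#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Parameters for the synthetic anagen-skin study generator
#'
#' A `SimParams` object bundles every knob of the synthetic-data module:
#' contig number and length law, base composition, per-library sequencing
#' depths, the planted differential-expression design, count overdispersion,
#' the functional-category design, SSR plants and the qPCR noise model.
#' All generators are pure functions of (inputs, seed): the same `SimParams`
#' always yields bit-identical data.
#'
#' @slot nContigs number of contigs to simulate.
#' @slot lengthMeanLog,lengthSdLog log-normal parameters of the contig
#'   length law (bp), truncated below at `minLength`; the defaults were
#'   calibrated against a published goat skin assembly summary (mean
#'   ~920-970 bp, N50 ~1380 bp, ~46% of contigs in 301-500 bp).
#' @slot minLength minimum contig length in bp (sampling is truncated at
#'   this floor); default 301, the usual "large contig" cutoff.
#' @slot gcFraction expected G+C fraction of simulated bases.
#' @slot libraryDepths named numeric vector of expected library totals
#'   (uniquely mapped reads); names are the library/sample ids and the FIRST
#'   library is the reference sample of every pairwise comparison.
#' @slot deFraction fraction of contigs with planted differential expression
#'   (applied in every non-reference library, half up, half down).
#' @slot deFold planted fold change (>= 1).
#' @slot dispersion negative-binomial overdispersion; 0 gives plain Poisson
#'   counts (the Audic-Claverie-consistent limit), > 0 gamma-mixes the
#'   per-library means.
#' @slot exprSdLog log-normal sd of per-contig relative expression levels;
#'   the default 1.5 reproduces the several-orders-of-magnitude per-contig
#'   coverage range seen in deep skin transcriptomes.
#' @slot nCategories number of functional categories (KOG-style clusters).
#' @slot enrichedCategoryEffect odds multiplier pulling planted DE contigs
#'   into the first category; 1 = no enrichment (null).
#' @slot annotatedFraction fraction of contigs carrying any annotation
#'   (mirrors real transcriptomes where most contigs have no category hit).
#' @slot ssrPlants list of `c(motif, repeats, contigIndex)` triplets (motif a
#'   character string, the other two coercible to integer) describing perfect
#'   tandem repeats to write into the simulated contigs.
#' @slot ctNoiseSd Gaussian sd of replicate Ct values in simulated qPCR.
#' @slot ctReplicates technical replicates per (gene, sample).
#' @slot seed integer master seed; all sub-generators derive their streams
#'   from it.
#'
#' @return `SimParams()` returns a validated `SimParams` object.
#' @examples
#' sp <- SimParams(nContigs = 50, seed = 7)
#' sp
#' @export
setClass("SimParams",
    representation(
        nContigs = "integer",
        lengthMeanLog = "numeric",
        lengthSdLog = "numeric",
        minLength = "integer",
        gcFraction = "numeric",
        libraryDepths = "numeric",
        deFraction = "numeric",
        deFold = "numeric",
        dispersion = "numeric",
        exprSdLog = "numeric",
        nCategories = "integer",
        enrichedCategoryEffect = "numeric",
        annotatedFraction = "numeric",
        ssrPlants = "list",
        ctNoiseSd = "numeric",
        ctReplicates = "integer",
        seed = "integer"
    )
)

setValidity("SimParams", function(object) {
    msg <- character(0)
    if (length(object@nContigs) != 1L || is.na(object@nContigs) ||
        object@nContigs < 0L)
        msg <- c(msg, "nContigs must be a single non-negative integer")
    if (object@minLength < 1L)
        msg <- c(msg, "minLength must be >= 1")
    if (object@lengthSdLog < 0)
        msg <- c(msg, "lengthSdLog must be >= 0")
    for (fr in c("gcFraction", "deFraction", "annotatedFraction")) {
        v <- slot(object, fr)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("%s must lie in [0, 1]", fr))
    }
    if (length(object@libraryDepths) < 1L || any(object@libraryDepths <= 0))
        msg <- c(msg, "libraryDepths must be positive")
    if (is.null(names(object@libraryDepths)) ||
        anyDuplicated(names(object@libraryDepths)))
        msg <- c(msg, "libraryDepths must carry unique sample names")
    if (object@deFold < 1)
        msg <- c(msg, "deFold must be >= 1")
    if (object@dispersion < 0)
        msg <- c(msg, "dispersion must be >= 0")
    if (object@exprSdLog < 0)
        msg <- c(msg, "exprSdLog must be >= 0")
    if (object@nCategories < 1L)
        msg <- c(msg, "nCategories must be >= 1")
    if (object@enrichedCategoryEffect <= 0)
        msg <- c(msg, "enrichedCategoryEffect must be > 0")
    if (object@ctNoiseSd < 0)
        msg <- c(msg, "ctNoiseSd must be >= 0")
    if (object@ctReplicates < 1L)
        msg <- c(msg, "ctReplicates must be >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' @rdname SimParams-class
#' @param nContigs,lengthMeanLog,lengthSdLog,minLength,gcFraction see slots.
#' @param libraryDepths,deFraction,deFold,dispersion,exprSdLog see slots.
#' @param nCategories,enrichedCategoryEffect,annotatedFraction see slots.
#' @param ssrPlants,ctNoiseSd,ctReplicates,seed see slots.
#' @export
SimParams <- function(nContigs = 5000L,
                      lengthMeanLog = -2.88,
                      lengthSdLog = 2.77,
                      minLength = 301L,
                      gcFraction = 0.549,
                      libraryDepths = c(BL = 2e6, BK = 2e6, BS = 2e6),
                      deFraction = 0.1,
                      deFold = 4,
                      dispersion = 0,
                      exprSdLog = 1.5,
                      nCategories = 25L,
                      enrichedCategoryEffect = 1,
                      annotatedFraction = 0.36,
                      ssrPlants = list(),
                      ctNoiseSd = 0.1,
                      ctReplicates = 3L,
                      seed = 1L) {
    if (is.null(names(libraryDepths)))
        names(libraryDepths) <- paste0("S", seq_along(libraryDepths))
    new("SimParams",
        nContigs = as.integer(nContigs),
        lengthMeanLog = lengthMeanLog,
        lengthSdLog = lengthSdLog,
        minLength = as.integer(minLength),
        gcFraction = gcFraction,
        libraryDepths = libraryDepths,
        deFraction = deFraction,
        deFold = deFold,
        dispersion = dispersion,
        exprSdLog = exprSdLog,
        nCategories = as.integer(nCategories),
        enrichedCategoryEffect = enrichedCategoryEffect,
        annotatedFraction = annotatedFraction,
        ssrPlants = ssrPlants,
        ctNoiseSd = ctNoiseSd,
        ctReplicates = as.integer(ctReplicates),
        seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nContigs, "contigs,",
        length(object@libraryDepths), "libraries (",
        paste(names(object@libraryDepths), collapse = ", "), ")\n")
    cat("  length ~ logN(", object@lengthMeanLog, ",", object@lengthSdLog,
        "), min", object@minLength, "bp; GC", object@gcFraction, "\n")
    cat("  DE fraction", object@deFraction, "at fold", object@deFold,
        "; dispersion", object@dispersion, "\n")
    cat("  categories:", object@nCategories, " enrichment effect:",
        object@enrichedCategoryEffect, " annotated:",
        object@annotatedFraction, "\n")
    cat("  SSR plants:", length(object@ssrPlants),
        " seed:", object@seed, "\n")
})

#' Contig-level count container for multi-library RNA-Seq comparisons
#'
#' `ContigCountSet` extends \linkS4class{SummarizedExperiment} with the
#' invariants this pipeline relies on: a single `"counts"` assay of
#' non-negative integers, a `length` column in `rowData()` (contig length in
#' bp, > 0), and a `libTotal` column in `colData()` holding each library's
#' total uniquely mapped reads (the N of both the Audic-Claverie statistic
#' and the RPKM denominator).
#'
#' @param counts integer matrix, contigs x libraries, with dimnames.
#' @param lengths per-contig lengths in bp, recycled against `rownames`.
#'   Either unnamed in row order or named by contig id.
#' @param libTotals per-library totals; defaults to `colSums(counts)`.
#'
#' @return a `ContigCountSet`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 9L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("BL", "BK")))
#' ccs <- ContigCountSet(m, lengths = c(400, 1200))
#' libTotals(ccs)
#' @aliases ContigCountSet
#' @export
setClass("ContigCountSet", contains = "SummarizedExperiment")

setValidity("ContigCountSet", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "contig ids (rownames) must be present and unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!"length" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'length' column")
    else if (any(is.na(rd$length)) || any(rd$length <= 0))
        msg <- c(msg, "contig lengths must be positive")
    cd <- SummarizedExperiment::colData(object)
    if (!"libTotal" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'libTotal' column")
    else if (any(is.na(cd$libTotal)) || any(cd$libTotal <= 0))
        msg <- c(msg, "library totals must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname ContigCountSet-class
#' @export
ContigCountSet <- function(counts, lengths, libTotals = colSums(counts)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must have contig ids as rownames")
    if (!is.null(names(lengths)))
        lengths <- lengths[rownames(counts)]
    if (length(lengths) != nrow(counts))
        stop("one length per contig is required")
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(length = as.numeric(lengths),
                            row.names = rownames(counts)),
        colData = DataFrame(libTotal = as.numeric(libTotals),
                            row.names = colnames(counts)))
    new("ContigCountSet", se)
}

setMethod("show", "ContigCountSet", function(object) {
    callNextMethod()
    cat("library totals:",
        paste(sprintf("%s=%g", colnames(object),
                      SummarizedExperiment::colData(object)$libTotal),
              collapse = ", "), "\n")
})
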
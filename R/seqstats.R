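#' Contig length distribution over assembly report bins
#'
#' Bins contig lengths into the inclusive intervals conventionally used in
#' de novo transcriptome reports: 301-500, 501-700, 701-1000, 1001-1500,
#' 1501-2000 and >2000 bp. The bins partition the length axis from the
#' first lower edge upward, so counts always sum to the number of input
#' contigs.
#'
#' @param lengths positive contig lengths in bp.
#' @param lowerEdges increasing integer lower bin edges; the last bin is
#'   open-ended.
#' @return data frame with `bin` labels, `count` and `totalBp` per bin.
#' @examples
#' lengthDistribution(c(350, 600, 2500))
#' @export
lengthDistribution <- function(lengths,
                               lowerEdges = c(301, 501, 701, 1001, 1501,
                                              2001)) {
    if (any(is.na(lengths)) || any(lengths <= 0))
        stop("contig lengths must be positive")
    if (is.unsorted(lowerEdges, strictly = TRUE))
        stop("'lowerEdges' must be strictly increasing")
    if (length(lengths) && any(lengths < lowerEdges[1L]))
        stop("lengths below the first bin edge (", lowerEdges[1L],
             " bp) are outside the binning scheme")
    breaks <- c(lowerEdges - 0.5, Inf)
    idx <- findInterval(lengths, breaks)
    upper <- c(lowerEdges[-1L] - 1, Inf)
    labs <- ifelse(is.finite(upper),
                   paste0(lowerEdges, "-", upper),
                   paste0(">", lowerEdges - 1))
    data.frame(
        bin = labs,
        count = vapply(seq_along(lowerEdges),
                       function(i) sum(idx == i), integer(1)),
        totalBp = vapply(seq_along(lowerEdges),
                         function(i) sum(lengths[idx == i]), numeric(1)))
}

#' N50 of an assembly
#'
#' The largest length L such that contigs of length >= L together cover at
#' least half the total assembly length.
#'
#' @param lengths positive contig lengths in bp (non-empty).
#' @return the N50 length in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1))   # 4
#' @export
n50 <- function(lengths) {
    if (length(lengths) == 0L)
        stop("cannot compute N50 of an empty assembly")
    if (any(is.na(lengths)) || any(lengths <= 0))
        stop("contig lengths must be positive")
    s <- sort(lengths, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' GC content of DNA sequences
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous `N` bases are excluded
#' from the denominator.
#'
#' @param x a [Biostrings::DNAStringSet], `DNAString`, or character vector
#'   of sequences over A/C/G/T/N.
#' @param pooled if `TRUE`, return the single GC fraction of all sequences
#'   pooled; otherwise one fraction per sequence.
#' @return numeric fraction(s) in [0, 1].
#' @examples
#' gcContent("ATGC")        # 0.5
#' gcContent("ANGT")        # 1/3
#' @export
gcContent <- function(x, pooled = FALSE) {
    x <- .asDNAStringSet(x)
    if (length(x) == 0L || any(Biostrings::width(x) == 0L))
        stop("sequences must be non-empty")
    freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T", "N"))
    if (any(rowSums(freq) != Biostrings::width(x)))
        stop("sequences must contain only A, C, G, T or N")
    if (pooled) freq <- matrix(colSums(freq), 1,
                               dimnames = list(NULL, colnames(freq)))
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    if (any(acgt == 0))
        stop("all-N sequences have no defined GC content")
    unname(rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt)
}

.asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
    if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
    stop("expected a DNAStringSet or character vector of DNA sequences")
}

# standard amino-acid class partition used for codon-usage summaries
.AA_CLASSES <- list(
    nonpolar = c("G", "A", "V", "L", "I", "P", "F", "M", "W", "C"),
    polarUncharged = c("S", "T", "Y", "N", "Q"),
    acidic = c("D", "E"),
    basic = c("K", "R", "H"))

#' Codon usage of predicted coding sequences
#'
#' Counts in-frame codons (read from position 1 of each CDS; trailing one
#' or two bases are ignored, codons containing N are tallied as ambiguous)
#' and summarises amino-acid class usage over sense codons with the
#' standard genetic code. Classes: nonpolar (G, A, V, L, I, P, F, M, W, C),
#' polar uncharged (S, T, Y, N, Q), acidic (D, E), basic (K, R, H); stop
#' codons (TAA, TAG, TGA) are tallied separately.
#'
#' @param cds CDS sequences, already in coding orientation (see
#'   [cdsSequences()]), as a `DNAStringSet` or character vector.
#' @return list with `codonCounts` (named vector over the 64 codons),
#'   `senseTotal`, `classCounts`, `classFractions` (over sense codons),
#'   `stopCounts` (TAA/TAG/TGA), `ambiguous` (codons containing N) and
#'   `gcFraction` of the counted CDS bases.
#' @examples
#' cu <- codonUsage("ATGGCTTAA")
#' cu$classFractions["nonpolar"]   # ATG + GCT are both nonpolar
#' @export
codonUsage <- function(cds) {
    cds <- .asDNAStringSet(cds)
    if (any(Biostrings::width(cds) < 3L))
        stop("every CDS must be at least one codon (3 bp) long")
    codonCounts <- colSums(Biostrings::trinucleotideFrequency(cds, step = 3))
    slots <- sum(Biostrings::width(cds) %/% 3L)
    aa <- vapply(names(codonCounts), function(cdn)
        Biostrings::GENETIC_CODE[[cdn]], character(1))
    stopCodons <- names(codonCounts)[aa == "*"]
    stopCounts <- codonCounts[c("TAA", "TAG", "TGA")]
    classCounts <- vapply(.AA_CLASSES, function(cls)
        sum(codonCounts[aa %in% cls]), numeric(1))
    senseTotal <- sum(codonCounts[!names(codonCounts) %in% stopCodons])
    stopifnot(sum(classCounts) == senseTotal)
    list(codonCounts = codonCounts,
         senseTotal = senseTotal,
         classCounts = classCounts,
         classFractions = if (senseTotal > 0) classCounts / senseTotal else
             classCounts * NA_real_,
         stopCounts = stopCounts,
         ambiguous = slots - sum(codonCounts),
         gcFraction = gcContent(cds, pooled = TRUE))
}

#' Extract CDS sequences from contigs
#'
#' Pulls each annotated coding region out of its contig using 1-based
#' inclusive coordinates and reverse-complements minus-strand records so
#' the returned sequences read 5' to 3' in coding orientation.
#'
#' @param contigs named [Biostrings::DNAStringSet] of contig sequences.
#' @param cdsTable data frame with columns `contig_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), and optionally `hasStart`/`hasStop` flags.
#' @return a `DNAStringSet` of CDS sequences, one per row of `cdsTable`.
#' @export
cdsSequences <- function(contigs, cdsTable) {
    if (!all(cdsTable$contig_id %in% names(contigs)))
        stop("CDS records reference unknown contigs")
    if (any(cdsTable$start < 1) |
        any(cdsTable$end > Biostrings::width(contigs)[
            match(cdsTable$contig_id, names(contigs))]) ||
        any(cdsTable$start > cdsTable$end))
        stop("CDS coordinates must satisfy 1 <= start <= end <= contig",
             " length")
    out <- Biostrings::subseq(contigs[cdsTable$contig_id],
                              start = cdsTable$start, end = cdsTable$end)
    minus <- cdsTable$strand == "-"
    if (any(minus))
        out[minus] <- Biostrings::reverseComplement(out[minus])
    out
}

#' Stop-codon usage frequencies
#'
#' Tallies the terminal codon of stop-containing coding sequences and
#' reports the relative use of TAA, TAG and TGA as percentages.
#'
#' @param cds stop-codon-containing CDS sequences in coding orientation.
#' @return list with `counts` and `percent` (one decimal; sums to 100
#'   within rounding) for TAA, TAG and TGA.
#' @examples
#' stopCodonFrequencies(c("ATGTGA", "ATGTGA", "ATGTAA", "ATGTAG"))$percent
#' @export
stopCodonFrequencies <- function(cds) {
    cds <- .asDNAStringSet(cds)
    if (length(cds) == 0L)
        stop("no stop-containing CDS records supplied")
    term <- as.character(Biostrings::subseq(
        cds, start = Biostrings::width(cds) - 2L))
    bad <- !term %in% c("TAA", "TAG", "TGA")
    if (any(bad))
        stop("terminal triplet is not a stop codon for record(s): ",
             paste(which(bad), collapse = ", "), " (",
             paste(unique(term[bad]), collapse = ", "), ")")
    counts <- vapply(c(TAA = "TAA", TAG = "TAG", TGA = "TGA"),
                     function(sc) sum(term == sc), integer(1))
    list(counts = counts, percent = round(100 * counts / sum(counts), 1))
}

#' Coding-sequence accounting
#'
#' Summarises a CDS annotation: how many contigs carry one, two, three, ...
#' predicted CDSs; how many CDSs fall in each completeness class (full =
#' start and stop codon present, start-only, stop-only, neither); and the
#' mean CDS length per class. Totals reconcile: the multiplicity-weighted
#' contig counts, the completeness classes and the record count all give
#' the same CDS total.
#'
#' @param cdsTable data frame with columns `contig_id`, `start`, `end`,
#'   `hasStart`, `hasStop` (logical).
#' @return list with `contigsByMultiplicity` (named count vector),
#'   `completeness` (counts for full / startOnly / stopOnly / neither),
#'   `meanLength` per completeness class, `nContigsWithCds` and `totalCds`.
#' @examples
#' cdsAccounting(data.frame(contig_id = c("c1", "c1", "c2"),
#'     start = 1, end = 300, hasStart = TRUE,
#'     hasStop = c(TRUE, FALSE, TRUE)))
#' @export
cdsAccounting <- function(cdsTable) {
    if (nrow(cdsTable) == 0L)
        return(list(contigsByMultiplicity = integer(0),
                    completeness = c(full = 0L, startOnly = 0L,
                                     stopOnly = 0L, neither = 0L),
                    meanLength = c(full = NaN, startOnly = NaN,
                                   stopOnly = NaN, neither = NaN),
                    nContigsWithCds = 0L, totalCds = 0L))
    need <- c("contig_id", "start", "end", "hasStart", "hasStop")
    if (!all(need %in% names(cdsTable)))
        stop("'cdsTable' needs columns: ", paste(need, collapse = ", "))
    mult <- table(table(cdsTable$contig_id))
    cls <- with(cdsTable, ifelse(hasStart & hasStop, "full",
                ifelse(hasStart, "startOnly",
                ifelse(hasStop, "stopOnly", "neither"))))
    lens <- cdsTable$end - cdsTable$start + 1
    classes <- c("full", "startOnly", "stopOnly", "neither")
    completeness <- vapply(classes, function(cc) sum(cls == cc), integer(1))
    meanLength <- vapply(classes, function(cc)
        if (any(cls == cc)) mean(lens[cls == cc]) else NaN, numeric(1))
    out <- list(
        contigsByMultiplicity = stats::setNames(as.integer(mult),
                                                names(mult)),
        completeness = completeness,
        meanLength = meanLength,
        nContigsWithCds = length(unique(cdsTable$contig_id)),
        totalCds = nrow(cdsTable))
    stopifnot(sum(as.integer(names(mult)) * as.integer(mult)) ==
              out$totalCds,
              sum(completeness) == out$totalCds)
    out
}
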
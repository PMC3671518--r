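#' Detect perfect simple sequence repeats (microsatellites)
#'
#' Scans DNA sequences for perfect tandem repeats of 2-6 bp motifs whose
#' full-copy span reaches at least `minTotalLen` bp (the classic "di- to
#' hexanucleotide, >= 18 bp" transcriptome SSR definition). Only maximal
#' runs are reported; repeat counts and spans cover full motif copies only
#' (a trailing partial copy extends neither). Motifs are primitive: a
#' (AT)x10 run is reported with unit AT, never ATAT. Overlapping candidate
#' runs of different unit sizes are resolved deterministically: longer span
#' first, then left-most, then shorter unit. `N` bases break runs.
#'
#' @param x a named [Biostrings::DNAStringSet] or character vector of
#'   uppercase DNA sequences (A/C/G/T/N).
#' @param minTotalLen minimum total repeat length in bp (default 18).
#' @param unitRange integer vector of motif lengths to scan (default 2:6).
#' @return a [GenomicRanges::GRanges] with one range per SSR (seqnames =
#'   contig id, 1-based inclusive coordinates) and metadata columns
#'   `motif`, `canonicalMotif`, `repeats`.
#' @examples
#' hits <- findSSRs(c(c1 = paste0("GGG", strrep("AC", 9), "TTT")))
#' as.character(hits$motif)    # "AC", 9 copies, 18 bp
#' @export
findSSRs <- function(x, minTotalLen = 18L, unitRange = 2:6) {
    x <- .asDNAStringSet(x)
    if (is.null(names(x)))
        names(x) <- paste0("seq", seq_along(x))
    if (minTotalLen < 1L || any(unitRange < 1L))
        stop("'minTotalLen' and 'unitRange' must be positive")
    hitList <- lapply(seq_along(x), function(i) {
        h <- .scanSSROne(as.character(x[[i]]), minTotalLen, unitRange)
        if (nrow(h)) h$contig <- names(x)[i]
        h
    })
    hits <- do.call(rbind, hitList[vapply(hitList, nrow, integer(1)) > 0])
    if (is.null(hits))
        hits <- data.frame(start = integer(0), end = integer(0),
                           motif = character(0), repeats = integer(0),
                           contig = character(0))
    GenomicRanges::GRanges(
        seqnames = hits$contig,
        ranges = IRanges::IRanges(start = hits$start, end = hits$end),
        motif = hits$motif,
        canonicalMotif = vapply(hits$motif, canonicalMotif, character(1),
                                USE.NAMES = FALSE),
        repeats = hits$repeats)
}

# single-sequence scan. Maximal period-u regions are located by comparing
# the sequence against itself shifted by u (vectorised); every anchor
# position inside a region is a candidate hit whose span covers the full
# motif copies reachable from that anchor, so phase conflicts at region
# boundaries are resolved exactly like the left-to-right greedy
# (longest span, then left-most, then shortest unit) demands.
.scanSSROne <- function(s, minTotalLen, unitRange) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) && !all(chars %in% c("A", "C", "G", "T", "N")))
        stop("invalid characters in sequence: ",
             paste(setdiff(unique(chars), c("A", "C", "G", "T", "N")),
                   collapse = ", "))
    n <- length(chars)
    ok <- chars %in% c("A", "C", "G", "T")
    cand <- list()
    for (u in unitRange) {
        if (n < 2L * u) next
        eq <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u] &
            ok[seq_len(n - u)] & ok[seq_len(n - u) + u]
        r <- rle(eq)
        regEnds <- cumsum(r$lengths)
        regStarts <- regEnds - r$lengths + 1L
        for (j in which(r$values & r$lengths >= u)) {
            a <- regStarts[j]                  # region [a, B], period u
            B <- regEnds[j] + u
            for (p in a:(B - 2L * u + 1L)) {
                copies <- (B - p + 1L) %/% u
                span <- copies * u
                if (span < minTotalLen) next
                motif <- paste(chars[p:(p + u - 1L)], collapse = "")
                if (!.isPrimitive(motif)) next
                cand[[length(cand) + 1L]] <-
                    data.frame(start = p, end = p + span - 1L,
                               motif = motif, repeats = copies, unit = u)
            }
        }
    }
    if (length(cand) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          motif = character(0), repeats = integer(0)))
    cand <- do.call(rbind, cand)
    cand <- cand[order(-(cand$end - cand$start + 1L), cand$start,
                       cand$unit), ]
    keep <- logical(nrow(cand))
    occupied <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(cand))) {
        if (nrow(occupied) == 0 ||
            all(cand$start[i] > occupied[, 2] |
                cand$end[i] < occupied[, 1])) {
            keep[i] <- TRUE
            occupied <- rbind(occupied, c(cand$start[i], cand$end[i]))
        }
    }
    out <- cand[keep, c("start", "end", "motif", "repeats")]
    out[order(out$start), , drop = FALSE]
}

.isPrimitive <- function(motif) {
    u <- nchar(motif)
    for (d in seq_len(u - 1L)) {
        if (u %% d != 0L) next
        if (identical(strrep(substr(motif, 1L, d), u %/% d), motif))
            return(FALSE)
    }
    TRUE
}

#' Canonical representative of an SSR motif class
#'
#' SSR motifs are equivalent under rotation (phase of the repeat) and
#' reverse complement (strand); the canonical representative is the
#' lexicographic minimum over all rotations of the motif and of its
#' reverse complement, so e.g. GT, TG, CA all canonicalise to AC and the
#' class is reported as "AC/GT".
#'
#' @param motif a primitive DNA motif of 2-6 bp.
#' @return the canonical motif string.
#' @examples
#' canonicalMotif("GT")    # "AC"
#' canonicalMotif("CTG")   # "AGC"
#' @export
canonicalMotif <- function(motif) {
    motif <- toupper(motif)
    u <- nchar(motif)
    if (u < 2L || u > 6L ||
        !all(strsplit(motif, "")[[1]] %in% c("A", "C", "G", "T")))
        stop("motif must be a 2-6 bp DNA string")
    if (!.isPrimitive(motif))
        stop("motif '", motif, "' is not primitive")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    rots <- function(m) vapply(seq_len(u), function(i)
        paste0(substr(m, i, u), substr(m, 1L, i - 1L)), character(1))
    min(c(rots(motif), rots(rc)))
}

#' Occurrence frequency of SSRs in an assembly
#'
#' Percentage of contigs per SSR: 100 x (number of SSRs) / (number of
#' contigs), reported to two decimals.
#'
#' @param nHits total number of SSRs found.
#' @param nContigs total number of contigs scanned.
#' @return percentage, rounded to two decimals.
#' @examples
#' ssrOccurrenceFrequency(2011, 49115)   # 4.09
#' @export
ssrOccurrenceFrequency <- function(nHits, nContigs) {
    if (nContigs <= 0) stop("nContigs must be positive")
    round(100 * nHits / nContigs, 2)
}

#' Mean inter-SSR distance in an assembly
#'
#' Total assembly length divided by the number of SSRs, in kilobases.
#'
#' @param totalBp total assembly size in bp.
#' @param nHits total number of SSRs; if 0 the distance is undefined and
#'   `NA` is returned.
#' @return mean distance in kb, rounded to one decimal (`NA` if no hits).
#' @examples
#' ssrMeanDistance(45.4e6, 2011)   # 22.6
#' @export
ssrMeanDistance <- function(totalBp, nHits) {
    if (totalBp <= 0) stop("totalBp must be positive")
    if (nHits == 0) return(NA_real_)
    round(totalBp / nHits / 1000, 1)
}

#' Summarise SSR content of an assembly
#'
#' @param hits `GRanges` from [findSSRs()].
#' @param contigs the scanned contigs (a `DNAStringSet`), used for the
#'   contig count and total assembly size.
#' @return list with `totalSSRs`, `contigsWithSSR`, `contigsWithTwoPlus`,
#'   `occurrenceFrequency` (percent), `meanDistanceKb`, `unitFractions`
#'   (share of di- through hexanucleotide hits) and `motifFractions`
#'   (share per canonical motif, decreasing).
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = strrep("AC", 12)))
#' ssrSummary(findSSRs(ctg), ctg)$totalSSRs
#' @export
ssrSummary <- function(hits, contigs) {
    contigs <- .asDNAStringSet(contigs)
    nHits <- length(hits)
    perContig <- table(as.character(GenomicRanges::seqnames(hits)))
    unit <- nchar(as.character(hits$motif))
    unitNames <- c("2" = "di", "3" = "tri", "4" = "tetra", "5" = "penta",
                   "6" = "hexa")
    uf <- vapply(names(unitNames), function(u) sum(unit == as.integer(u)),
                 numeric(1))
    names(uf) <- unitNames
    mf <- sort(table(as.character(hits$canonicalMotif)),
               decreasing = TRUE) / max(nHits, 1L)
    list(totalSSRs = nHits,
         contigsWithSSR = length(perContig),
         contigsWithTwoPlus = sum(perContig >= 2),
         occurrenceFrequency = ssrOccurrenceFrequency(nHits,
                                                      length(contigs)),
         meanDistanceKb = ssrMeanDistance(sum(Biostrings::width(contigs)),
                                          nHits),
         unitFractions = if (nHits) uf / nHits else uf,
         motifFractions = mf)
}
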
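#' Read contig sequences from FASTA
#'
#' Thin validating wrapper over [Biostrings::readDNAStringSet()]:
#' sequences are uppercased, multi-line records are tolerated, duplicate
#' ids and empty files are errors.
#'
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readContigFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L)
        stop("no sequences found in ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate sequence id(s) in ", path, ": ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    Biostrings::DNAStringSet(toupper(x))
}

#' Write contig sequences to FASTA
#'
#' Fixed dialect for reproducible (byte-identical) outputs: 70-column
#' uppercase sequence lines.
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContigFasta <- function(contigs, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(toupper(contigs)),
                                path, width = 70L)
    invisible(path)
}

#' Read a contig count table
#'
#' Canonical count-table dialect: tab-separated, `#`-prefixed comment
#' lines, a header row of library ids, first column `contig_id`, one
#' non-negative integer column per library. Library totals are read from
#' an optional sidecar (tab-separated `sample`, `total`); without one they
#' default to the column sums.
#'
#' @param path count table path.
#' @param totalsPath optional totals sidecar path.
#' @param lengths optional named per-contig lengths (bp); default 1 for
#'   every contig (sufficient for count-only analyses).
#' @return a \linkS4class{ContigCountSet}.
#' @export
readCountTable <- function(path, totalsPath = NULL, lengths = NULL) {
    tab <- utils::read.delim(path, comment.char = "#",
                             check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 3L || names(tab)[1L] != "contig_id")
        stop("count table must have a 'contig_id' column plus >= 2",
             " library columns")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-integer or negative count at data line ", bad[1L, 1L],
             ", column '", colnames(m)[bad[1L, 2L]], "'")
    storage.mode(m) <- "integer"
    rownames(m) <- tab$contig_id
    totals <- colSums(m)
    if (!is.null(totalsPath)) {
        tt <- utils::read.delim(totalsPath, comment.char = "#")
        totals <- stats::setNames(tt$total, tt$sample)[colnames(m)]
        if (any(is.na(totals)))
            stop("totals sidecar is missing sample(s): ",
                 paste(colnames(m)[is.na(totals)], collapse = ", "))
    }
    if (is.null(lengths))
        lengths <- stats::setNames(rep(1, nrow(m)), rownames(m))
    ContigCountSet(m, lengths = lengths, libTotals = totals)
}

#' Write a contig count table
#'
#' @param counts a \linkS4class{ContigCountSet}.
#' @param path output path.
#' @param totalsPath optional path for a totals sidecar.
#' @param comment optional comment line(s) written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(counts, path, totalsPath = NULL,
                            comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment))
        writeLines(paste0("# ", comment), con)
    m <- SummarizedExperiment::assay(counts, "counts")
    tab <- data.frame(contig_id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(totalsPath))
        utils::write.table(
            data.frame(sample = colnames(counts),
                       total = unname(libTotals(counts))),
            totalsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a functional-category annotation table
#'
#' Tab-separated with columns `contig_id` and `categories`
#' (comma-separated category ids); `#` comments allowed.
#'
#' @param path annotation table path.
#' @return data frame with `contig_id`, `categories`.
#' @export
readCategoryTable <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#",
                             colClasses = "character")
    if (!all(c("contig_id", "categories") %in% names(tab)))
        stop("annotation table needs columns 'contig_id' and 'categories'")
    tab
}

#' Read a qPCR Ct table
#'
#' Tab-separated with columns `gene`, `sample`, `replicate`, `ct`.
#'
#' @param path Ct table path.
#' @return data frame.
#' @export
readCtTable <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#")
    if (!all(c("gene", "sample", "ct") %in% names(tab)))
        stop("Ct table needs columns 'gene', 'sample', 'ct'")
    tab
}

#' Read a CDS coordinate annotation table
#'
#' Tab-separated with columns `contig_id`, `start`, `end`, `strand`,
#' `hasStart`, `hasStop` (1-based inclusive coordinates).
#'
#' @param path CDS table path.
#' @return data frame.
#' @export
readCdsTable <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#")
    need <- c("contig_id", "start", "end", "strand", "hasStart", "hasStop")
    if (!all(need %in% names(tab)))
        stop("CDS table needs columns: ", paste(need, collapse = ", "))
    tab$hasStart <- as.logical(tab$hasStart)
    tab$hasStop <- as.logical(tab$hasStop)
    tab
}
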
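#' @importFrom stats rlnorm rpois rnbinom rnorm runif
NULL

# deterministic sub-stream seed derived from the master seed; kept inside
# the 32-bit integer range
.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) %% 1e9 + k * 1000003) %% 2147483647)
}

#' Simulate assembled transcriptome contigs
#'
#' Draws contig lengths from a truncated log-normal law (emulating a de
#' novo assembly averaging ~900 bp with a long right tail) and fills each
#' contig with independent bases at the configured GC fraction. Identical
#' parameters (including the seed) give bit-identical sequences.
#'
#' @param params a \linkS4class{SimParams}.
#' @return a named [Biostrings::DNAStringSet] (`contig000001`, ...).
#' @examples
#' ctg <- simulateContigs(SimParams(nContigs = 5, seed = 2))
#' Biostrings::width(ctg)
#' @export
simulateContigs <- function(params) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    n <- params@nContigs
    if (n == 0L)
        return(Biostrings::DNAStringSet())
    set.seed(.subSeed(params@seed, 1L))
    # truncated log-normal via inverse CDF (the truncation mass can be
    # large, so rejection sampling is not an option)
    pmin0 <- stats::plnorm(params@minLength - 0.5, params@lengthMeanLog,
                           params@lengthSdLog)
    len <- pmax(params@minLength,
                round(stats::qlnorm(runif(n, pmin0, 1),
                                    params@lengthMeanLog,
                                    params@lengthSdLog)))
    gc <- params@gcFraction
    bases <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    big <- paste(bases, collapse = "")
    ends <- cumsum(len)
    seqs <- substring(big, ends - len + 1, ends)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("contig%06d", seq_len(n))
    out
}

#' Plant perfect SSRs into simulated contigs
#'
#' Overwrites a stretch of each targeted contig with `motif` repeated
#' `repeats` times (total span `nchar(motif) * repeats` bp), at a
#' seed-determined position; contig lengths are unchanged. The returned
#' truth table records the exact 1-based inclusive span of every plant.
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param ssrPlants list of `c(motif, repeats, contigIndex)` triplets.
#' @param seed integer seed for the placement stream.
#' @return list with `contigs` (modified set) and `truth` (data frame:
#'   `contig_id`, `start`, `end`, `motif`, `repeats`).
#' @examples
#' ctg <- simulateContigs(SimParams(nContigs = 2, seed = 2))
#' pl <- plantSSRs(ctg, list(list("AC", 9, 1)), seed = 7)
#' pl$truth
#' @export
plantSSRs <- function(contigs, ssrPlants, seed = 1L) {
    truth <- data.frame(contig_id = character(0), start = integer(0),
                        end = integer(0), motif = character(0),
                        repeats = integer(0))
    if (length(ssrPlants) == 0L)
        return(list(contigs = contigs, truth = truth))
    set.seed(.subSeed(seed, 2L))
    for (pl in ssrPlants) {
        motif <- toupper(as.character(pl[[1]]))
        reps <- as.integer(pl[[2]])
        idx <- as.integer(pl[[3]])
        if (idx < 1L || idx > length(contigs))
            stop("SSR plant targets contig index ", idx,
                 " outside the contig set")
        span <- nchar(motif) * reps
        L <- Biostrings::width(contigs)[idx]
        if (span > L)
            stop("SSR plant of ", span, " bp does not fit in contig ",
                 names(contigs)[idx], " (", L, " bp)")
        start <- sample.int(L - span + 1L, 1L)
        Biostrings::subseq(contigs[[idx]], start,
                           start + span - 1L) <- Biostrings::DNAString(
                               strrep(motif, reps))
        truth <- rbind(truth, data.frame(
            contig_id = names(contigs)[idx], start = start,
            end = start + span - 1L, motif = motif, repeats = reps))
    }
    list(contigs = contigs, truth = truth)
}

#' Simulate a multi-library count matrix with planted differential
#' expression
#'
#' Per-contig relative expression levels are log-normal (wide dynamic
#' range); the expected count of contig c in library s is
#' `depth_s * expr_c * length_c * fold_{c,s} / sum(expr * length)`.
#' A `deFraction` of contigs is planted as differentially expressed: half
#' have their expression multiplied by `deFold` in every non-reference
#' library (consistently "up" versus the first, reference library), half
#' divided. Counts are Poisson draws around these means, or gamma-mixed
#' (negative binomial with size `1/dispersion`) when `dispersion > 0`.
#' Recorded library totals are the realised column sums.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (only lengths are
#'   used).
#' @param params a \linkS4class{SimParams} with >= 2 libraries.
#' @return list with `counts` (a \linkS4class{ContigCountSet}) and `truth`
#'   (list: `deUp`, `deDown` contig ids, `foldChange` named vector of
#'   treatment/reference folds, `comparisons` labels, `reference`).
#' @examples
#' ctg <- simulateContigs(SimParams(nContigs = 100, seed = 2))
#' sim <- simulateCounts(ctg, SimParams(nContigs = 100,
#'     libraryDepths = c(BL = 1e5, BK = 1e5), seed = 2))
#' head(SummarizedExperiment::assay(sim$counts))
#' @export
simulateCounts <- function(contigs, params) {
    stopifnot(is(params, "SimParams"))
    depths <- params@libraryDepths
    if (length(depths) < 2L)
        stop("at least two libraries are required")
    n <- length(contigs)
    if (n == 0L) stop("no contigs supplied")
    set.seed(.subSeed(params@seed, 3L))
    len <- Biostrings::width(contigs)
    expr <- rlnorm(n, 0, params@exprSdLog)
    w <- expr * len
    nDE <- round(params@deFraction * n)
    de <- sample(names(contigs), nDE)
    up <- de[seq_len(nDE %/% 2)]
    down <- setdiff(de, up)
    fold <- rep(1, n); names(fold) <- names(contigs)
    fold[up] <- params@deFold
    fold[down] <- 1 / params@deFold
    S <- length(depths)
    F <- matrix(1, n, S, dimnames = list(names(contigs), names(depths)))
    # balanced planting: up-regulated contigs are elevated in every
    # treatment library, down-regulated ones elevated in the reference --
    # relative (treatment/reference) folds are identical, but planted
    # effects inflate all library totals comparably, as in real compositional
    # mRNA pools, instead of systematically biasing the treatment totals
    F[up, -1L] <- params@deFold
    F[down, 1L] <- params@deFold
    mu <- sweep(F * w, 2, depths / sum(w), "*")
    counts <- if (params@dispersion == 0)
        rpois(n * S, mu)
    else
        rnbinom(n * S, size = 1 / params@dispersion, mu = mu)
    counts <- matrix(as.integer(counts), n, S,
                     dimnames = dimnames(mu))
    truth <- list(deUp = up, deDown = down,
                  foldChange = fold[de],
                  comparisons = paste0(names(depths)[1L], "_vs_",
                                       names(depths)[-1L]),
                  reference = names(depths)[1L])
    list(counts = ContigCountSet(counts, lengths = len), truth = truth)
}

#' Assign functional categories with one optionally enriched category
#'
#' An `annotatedFraction` of contigs receives one (occasionally two)
#' category labels out of `nCategories` KOG-style clusters. For planted DE
#' contigs the odds of the first category (`"C01"`) are multiplied by
#' `enrichedCategoryEffect`, creating a known enriched cluster; effect 1
#' gives the null. Unannotated contigs carry no row, mirroring real
#' transcriptomes where most contigs lack a category hit.
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param params a \linkS4class{SimParams}.
#' @param truth the truth list from [simulateCounts()] (used for the DE
#'   ids); may be `NULL` for a fully null assignment.
#' @return data frame with `contig_id` and `categories` (comma-separated).
#' @export
simulateCategories <- function(contigs, params, truth = NULL) {
    stopifnot(is(params, "SimParams"))
    if (params@nCategories < 2L)
        stop("at least two categories are required")
    set.seed(.subSeed(params@seed, 4L))
    ids <- names(contigs)
    ann <- sort(sample(ids, round(params@annotatedFraction * length(ids))))
    if (length(ann) == 0L)
        return(data.frame(contig_id = character(0),
                          categories = character(0)))
    cats <- sprintf("C%02d", seq_len(params@nCategories))
    deIds <- unique(c(truth$deUp, truth$deDown))
    pick <- function(isDE) {
        pr <- rep(1, params@nCategories)
        if (isDE) pr[1L] <- params@enrichedCategoryEffect
        sample(cats, 1L, prob = pr)
    }
    primary <- vapply(ann %in% deIds, pick, character(1))
    extra <- runif(length(ann)) < 0.15
    categories <- primary
    if (any(extra)) {
        second <- vapply(which(extra), function(i)
            sample(setdiff(cats, primary[i]), 1L), character(1))
        categories[extra] <- paste(primary[extra], second, sep = ",")
    }
    data.frame(contig_id = ann, categories = categories)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' For up to `nGenes` planted DE contigs, emits replicate Ct values for a
#' target and a reference gene across every library/sample such that
#' `Ct_target - Ct_reference = dCt0 - log2(fold)` plus Gaussian noise of sd
#' `ctNoiseSd`; the reference gene's Ct is constant in expectation across
#' samples and the first library is the calibrator (fold 1). With zero
#' noise the 2^-ddCt method recovers the planted folds exactly.
#'
#' @param truth the truth list from [simulateCounts()].
#' @param params a \linkS4class{SimParams}.
#' @param nGenes maximum number of target genes (default 10).
#' @param referenceGene id used for the normaliser rows (default
#'   `"REFG"`).
#' @return data frame with `gene`, `sample`, `replicate`, `ct`.
#' @export
simulateQpcr <- function(truth, params, nGenes = 10L,
                         referenceGene = "REFG") {
    stopifnot(is(params, "SimParams"))
    if (is.null(truth$foldChange) || length(truth$foldChange) == 0L)
        stop("truth carries no planted fold changes")
    set.seed(.subSeed(params@seed, 5L))
    genes <- names(truth$foldChange)
    genes <- genes[seq_len(min(nGenes, length(genes)))]
    samples <- names(params@libraryDepths)
    reps <- params@ctReplicates
    refCt <- 15
    dCt0 <- stats::setNames(runif(length(genes), 2, 8), genes)
    rows <- expand.grid(gene = c(genes, referenceGene), sample = samples,
                        replicate = seq_len(reps),
                        stringsAsFactors = FALSE)
    isRef <- rows$gene == referenceGene
    fold <- ifelse(isRef | rows$sample == samples[1L], 1,
                   truth$foldChange[rows$gene])
    mu <- ifelse(isRef, refCt, refCt + dCt0[rows$gene] - log2(fold))
    rows$ct <- mu + rnorm(nrow(rows), 0, params@ctNoiseSd)
    rows[order(rows$gene, rows$sample, rows$replicate), ]
}

#' Simulate a complete synthetic anagen-skin study
#'
#' Chains every generator: contigs, SSR plants, the multi-library count
#' matrix with planted differential expression, the category annotation
#' with an optionally enriched cluster, and a concordant qPCR Ct table.
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with `contigs`, `counts` (\linkS4class{ContigCountSet}),
#'   `annotation`, `ct`, `truth` (DE ids and folds, SSR spans, enriched
#'   category id) and `params`.
#' @examples
#' sim <- simulateStudy(SimParams(nContigs = 100, seed = 4,
#'     libraryDepths = c(BL = 1e5, BK = 1e5)))
#' names(sim)
#' @export
simulateStudy <- function(params) {
    contigs <- simulateContigs(params)
    pl <- plantSSRs(contigs, params@ssrPlants, seed = params@seed)
    cm <- simulateCounts(pl$contigs, params)
    annotation <- simulateCategories(pl$contigs, params, cm$truth)
    ct <- if (length(cm$truth$foldChange))
        simulateQpcr(cm$truth, params) else NULL
    truth <- cm$truth
    truth$ssr <- pl$truth
    truth$enrichedCategory <- if (params@enrichedCategoryEffect > 1)
        "C01" else NA_character_
    list(contigs = pl$contigs, counts = cm$counts,
         annotation = annotation, ct = ct, truth = truth, params = params)
}
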
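test_that("contig generation honours size, floor, GC and determinism", {
    expect_length(simulateContigs(SimParams(nContigs = 0L)), 0L)

    p <- SimParams(nContigs = 400L, seed = 11L)
    ctg <- simulateContigs(p)
    expect_length(ctg, 400L)
    expect_true(all(Biostrings::width(ctg) >= 301L))
    expect_identical(as.character(ctg),
                     as.character(simulateContigs(p)))  # same seed, same bytes

    # pooled GC within 3 binomial standard errors of the target
    p2 <- SimParams(nContigs = 2000L, gcFraction = 0.5, seed = 5L)
    ctg2 <- simulateContigs(p2)
    nb <- sum(Biostrings::width(ctg2))
    se <- sqrt(0.5 * 0.5 / nb)
    expect_lt(abs(gcContent(ctg2, pooled = TRUE) - 0.5), 3 * se)
})

test_that("FASTA round trip is byte-identical under a fixed seed", {
    p <- SimParams(nContigs = 20L, seed = 3L)
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    writeContigFasta(simulateContigs(p), f1)
    writeContigFasta(simulateContigs(p), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    back <- readContigFasta(f1)
    expect_identical(as.character(back),
                     as.character(simulateContigs(p)))
})

test_that("SSR plants are written verbatim at the recorded span", {
    p <- SimParams(nContigs = 3L, seed = 9L)
    ctg <- simulateContigs(p)
    pl <- plantSSRs(ctg, list(list("AC", 9, 1), list("AGC", 7, 2)),
                    seed = 9L)
    expect_identical(Biostrings::width(pl$contigs), Biostrings::width(ctg))
    for (i in seq_len(nrow(pl$truth))) {
        tr <- pl$truth[i, ]
        got <- as.character(Biostrings::subseq(
            pl$contigs[[match(tr$contig_id, names(pl$contigs))]],
            tr$start, tr$end))
        expect_identical(got, strrep(tr$motif, tr$repeats))
    }
    # empty plant list is the identity
    same <- plantSSRs(ctg, list(), seed = 1L)
    expect_identical(as.character(same$contigs), as.character(ctg))
    expect_identical(nrow(same$truth), 0L)
    # a plant that cannot fit is a bounds error
    expect_error(plantSSRs(ctg, list(list("ACGTAC", 1000, 1)), seed = 1L),
                 "does not fit")
})

test_that("planted SSRs are recovered exactly by the scanner", {
    p <- SimParams(nContigs = 5L, seed = 21L,
                   ssrPlants = list(list("AC", 9, 1), list("AGC", 7, 2),
                                    list("AAGT", 6, 3)))
    sim <- simulateStudy(p)
    hits <- findSSRs(sim$contigs)
    # recovery is phase-tolerant: flanking bases can extend a planted run,
    # shifting the maximal span by up to one unit, but the locus and the
    # canonical motif must match and the hit must be at least as long
    for (i in seq_len(nrow(sim$truth$ssr))) {
        tr <- sim$truth$ssr[i, ]
        u <- nchar(tr$motif)
        j <- which(as.character(GenomicRanges::seqnames(hits)) ==
                       tr$contig_id &
                   GenomicRanges::start(hits) <= tr$start + u &
                   GenomicRanges::end(hits) >= tr$end - u &
                   GenomicRanges::width(hits) >= tr$end - tr$start + 1 - u)
        expect_length(j, 1L)
        expect_identical(canonicalMotif(as.character(hits$motif[j])),
                         canonicalMotif(tr$motif))
        expect_gte(GenomicRanges::width(hits[j]), 18L)
    }
})

test_that("count generation obeys the planted design", {
    p <- SimParams(nContigs = 600L, seed = 13L, deFold = 4,
                   libraryDepths = c(BL = 3e5, BK = 3e5))
    ctg <- simulateContigs(p)
    sim <- simulateCounts(ctg, p)
    m <- SummarizedExperiment::assay(sim$counts, "counts")

    # conservation: recorded totals are the realised column sums
    expect_identical(unname(libTotals(sim$counts)), unname(colSums(m)))
    # determinism
    expect_identical(m, SummarizedExperiment::assay(
        simulateCounts(ctg, p)$counts, "counts"))
    # truth ids are generated ids and splits are disjoint
    expect_true(all(c(sim$truth$deUp, sim$truth$deDown) %in% names(ctg)))
    expect_length(intersect(sim$truth$deUp, sim$truth$deDown), 0L)

    # null symmetry: without DE and equal depths the mean count difference
    # across contigs is ~0
    p0 <- SimParams(nContigs = 2000L, seed = 17L, deFraction = 0,
                    libraryDepths = c(BL = 1e6, BK = 1e6))
    s0 <- simulateCounts(simulateContigs(p0), p0)
    m0 <- SummarizedExperiment::assay(s0$counts, "counts")
    d <- m0[, 2] - m0[, 1]
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(nrow(m0)))

    expect_error(simulateCounts(ctg, SimParams(nContigs = 600L,
        libraryDepths = c(BL = 1e5))), "two libraries")
})

test_that("planted fold is recovered in Monte-Carlo count ratios", {
    # flat expression so every contig is deeply covered; across replicate
    # draws the BK/BL count ratio of an up-planted contig must sit within
    # three standard errors of the planted fold 4
    p <- SimParams(nContigs = 50L, seed = 31L, deFraction = 0.04,
                   deFold = 4, exprSdLog = 0,
                   libraryDepths = c(BL = 5e5, BK = 5e5))
    ctg <- simulateContigs(p)
    ratios <- vapply(seq_len(300), function(i) {
        pi <- p; pi@seed <- 1000L + i
        sim <- simulateCounts(ctg, pi)
        m <- SummarizedExperiment::assay(sim$counts, "counts")
        up <- sim$truth$deUp[1]
        m[up, "BK"] / m[up, "BL"]
    }, numeric(1))
    se <- sd(ratios) / sqrt(length(ratios))
    expect_lt(abs(mean(ratios) - 4), 3 * se)
})

test_that("category assignment annotates a known fraction with a planted
           enriched cluster", {
    p <- SimParams(nContigs = 1000L, seed = 23L,
                   enrichedCategoryEffect = 30, deFraction = 0.2,
                   annotatedFraction = 0.5, nCategories = 10L)
    sim <- simulateStudy(p)
    ann <- sim$annotation
    expect_true(all(ann$contig_id %in% names(sim$contigs)))
    expect_equal(nrow(ann), 500L)
    expect_true(all(nzchar(ann$categories)))
    # with a strong effect the enriched category dominates DE contigs
    deAnn <- ann[ann$contig_id %in%
                     c(sim$truth$deUp, sim$truth$deDown), ]
    firstCat <- vapply(strsplit(deAnn$categories, ","), `[`, "", 1)
    expect_gt(mean(firstCat == "C01"), 0.5)
    # zero annotation propagates to an empty-background error downstream
    p0 <- SimParams(nContigs = 50L, annotatedFraction = 0, seed = 2L)
    s0 <- simulateStudy(p0)
    expect_error(enrichCategories(s0$truth$deUp, s0$annotation,
                                  names(s0$contigs)),
                 "empty annotated background")
})

test_that("simulated Ct tables encode the planted folds", {
    p <- SimParams(nContigs = 200L, deFold = 4, ctNoiseSd = 0, seed = 41L)
    sim <- simulateStudy(p)
    ct <- sim$ct
    expect_true(all(c("gene", "sample", "replicate", "ct") %in% names(ct)))
    # noise-free: ddCt recovers the planted fold exactly, fold 1 at the
    # calibrator
    for (g in head(names(sim$truth$foldChange), 4)) {
        expect_equal(ddctFoldChange(ct, g, "REFG", "BK", "BL"),
                     unname(sim$truth$foldChange[g]))
        expect_equal(ddctFoldChange(ct, g, "REFG", "BL", "BL"), 1)
    }
    # reference-gene Ct constant across samples when noise-free
    refCt <- ct$ct[ct$gene == "REFG"]
    expect_equal(max(refCt) - min(refCt), 0)
})
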
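.toyCounts <- function() {
    m <- matrix(c(1000L, 0L, 40L,
                  2500L, 10L, 40L), ncol = 2,
                dimnames = list(c("c1", "c2", "c3"), c("BL", "BK")))
    ContigCountSet(m, lengths = c(1000, 500, 800),
                   libTotals = c(1e6, 1e6))
}

test_that("RPKM follows its defining formula", {
    ccs <- .toyCounts()
    rpkm <- computeRPKM(ccs)
    expect_equal(rpkm["c1", "BL"], 1e9 * 1000 / (1e6 * 1000))  # 1000
    expect_equal(rpkm["c2", "BL"], 0)                          # zero count
    # doubling a library total halves its RPKM column
    ccs2 <- ContigCountSet(SummarizedExperiment::assay(ccs),
                           lengths = contigLengths(ccs),
                           libTotals = c(2e6, 1e6))
    expect_equal(computeRPKM(ccs2)[, "BL"], rpkm[, "BL"] / 2)
    expect_error(computeRPKM(SummarizedExperiment::assay(ccs),
                             lengths = c(0, 1, 1), libTotals = c(1, 1)),
                 "positive")
})

test_that("DEG calling applies both criteria with inclusive folds", {
    ccs <- .toyCounts()
    calls <- callDEGs(ccs, c("BL", "BK"))
    # c1: pseudocount-stabilised fold (2501/1001), clearly significant
    expect_equal(unname(calls["c1", "foldChange"]), 2501 / 1001)
    expect_true(unname(calls["c1", "significant"]))
    expect_identical(unname(calls["c1", "direction"]), "up")
    # c3: identical counts, fold 1, never significant
    expect_false(unname(calls["c3", "significant"]))
    # thresholds are inclusive: a contig at exactly 2-fold passes
    m <- matrix(c(999L, 1999L), 1, dimnames = list("c", c("A", "B")))
    one <- callDEGs(ContigCountSet(m, lengths = 500,
                                   libTotals = c(1e6, 1e6)), c("A", "B"),
                    qThreshold = 1)
    expect_equal(unname(one["c", "foldChange"]), 2)
    expect_true(unname(one["c", "significant"]))
    expect_error(callDEGs(ccs, c("BL", "XX")), "name two libraries")
})

test_that("relaxing either threshold never removes a significant contig", {
    sim <- simulateStudy(SimParams(nContigs = 500L, deFold = 8, seed = 19L,
                                   libraryDepths = c(BL = 2e5, BK = 2e5)))
    strict <- callDEGs(sim$counts, c("BL", "BK"),
                       qThreshold = 1e-3, fcThreshold = 2)
    looseQ <- callDEGs(sim$counts, c("BL", "BK"),
                       qThreshold = 1e-2, fcThreshold = 2)
    looseF <- callDEGs(sim$counts, c("BL", "BK"),
                       qThreshold = 1e-3, fcThreshold = 1.5)
    sigIds <- function(z) rownames(z)[z$significant]
    expect_true(all(sigIds(strict) %in% sigIds(looseQ)))
    expect_true(all(sigIds(strict) %in% sigIds(looseF)))
})

test_that("swapping the two libraries mirrors directions", {
    sim <- simulateStudy(SimParams(nContigs = 400L, deFold = 8, seed = 29L,
                                   libraryDepths = c(BL = 2e5, BK = 2e5)))
    ab <- callDEGs(sim$counts, c("BL", "BK"))
    ba <- callDEGs(sim$counts, c("BK", "BL"))
    expect_identical(ab$significant, ba$significant)
    sig <- ab$significant
    expect_identical(ab$direction[sig] == "up", ba$direction[sig] == "down")
    expect_equal(ab$foldChange, 1 / ba$foldChange)
})

test_that("consistency analysis intersects up and down sets", {
    mk <- function(ids, dirs, label, ref) {
        d <- S4Vectors::DataFrame(direction = dirs,
                                  significant = rep(TRUE, length(ids)),
                                  row.names = ids)
        S4Vectors::metadata(d) <- list(label = label, reference = ref)
        d
    }
    a <- mk(c("a", "b", "c", "z"), c("up", "up", "up", "down"),
            "BL_vs_BK", "BL")
    b <- mk(c("b", "c", "d", "y"), c("up", "up", "up", "down"),
            "BL_vs_BS", "BL")
    v <- consistentDEGs(a, b)
    expect_setequal(v$consistentUp, c("b", "c"))
    expect_identical(v$nConsistentUp, 2L)
    expect_identical(v$nConsistentDown, 0L)   # disjoint down sets
    expect_identical(v$totalConsistent, 2L)
    # orientation mismatch is a contract error
    bBad <- mk("b", "up", "BK_vs_BS", "BK")
    expect_error(consistentDEGs(a, bBad), "reference")
})

test_that("mapping rates reproduce printed library summaries", {
    tab <- data.frame(
        sample = c("BL", "BK", "BS"),
        totalReads = c(41232601, 39363238, 49962602),
        cleanReads = c(40731588, 38876298, 49337308),
        mappedReads = c(35593595, 34033557, 42383188))
    expect_equal(mappingSummary(tab)$mappedPerClean, c(87.4, 87.5, 85.9))
    ident <- data.frame(sample = "x", totalReads = 10, cleanReads = 10,
                        mappedReads = 10)
    expect_equal(mappingSummary(ident)$mappedPerClean, 100.0)
    expect_error(mappingSummary(transform(ident, cleanReads = 0)),
                 "positive")
    expect_error(mappingSummary(transform(ident, mappedReads = 11)))
})
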
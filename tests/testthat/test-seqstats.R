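test_that("length distribution bins and conserves", {
    d <- lengthDistribution(c(350, 600, 2500))
    expect_equal(d$count, c(1, 1, 0, 0, 0, 1))
    expect_identical(d$bin[1], "301-500")
    expect_identical(d$bin[6], ">2000")
    expect_equal(sum(d$count), 3)
    expect_equal(sum(d$totalBp), 350 + 600 + 2500)
    # empty input keeps the bin frame, all zero
    expect_equal(lengthDistribution(numeric(0))$count, rep(0L, 6))
    expect_error(lengthDistribution(c(400, -2)), "positive")
    expect_error(lengthDistribution(100), "outside")
    # conservation on random inputs
    set.seed(2)
    for (i in 1:20) {
        l <- sample(301:5000, sample(1:200, 1), TRUE)
        d <- lengthDistribution(l)
        expect_equal(sum(d$count), length(l))
        expect_equal(sum(d$totalBp), sum(l))
    }
})

test_that("N50 agrees with the brute-force definition", {
    expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
    expect_equal(n50(10), 10)
    expect_equal(n50(rep(7, 13)), 7)
    expect_error(n50(numeric(0)), "empty")
    set.seed(3)
    for (i in 1:50) {
        l <- sample(1:2000, sample(1:200, 1), TRUE)
        expect_equal(n50(l), n50Oracle(l))
    }
})

test_that("GC content counts G+C over unambiguous bases", {
    expect_equal(gcContent("ATGC"), 0.5)
    expect_equal(gcContent("GGCC"), 1.0)
    expect_equal(gcContent("ANGT"), 1 / 3)
    expect_equal(gcContent(c("AT", "GC"), pooled = TRUE), 0.5)
    expect_error(gcContent("NNN"), "GC content")
    expect_error(gcContent(""), "non-empty")
    expect_error(gcContent("ATXG"))   # rejected at DNA parsing
})

test_that("codon usage counts in-frame codons and classes", {
    cu <- codonUsage("ATGGCTTAA")
    expect_equal(unname(cu$codonCounts[c("ATG", "GCT", "TAA")]),
                 c(1, 1, 1))
    expect_equal(sum(cu$codonCounts), 3)
    expect_equal(unname(cu$classFractions["nonpolar"]), 1)  # M and A
    expect_equal(unname(cu$stopCounts["TAA"]), 1)
    # trailing bases are ignored
    cu2 <- codonUsage("ATGA")
    expect_equal(sum(cu2$codonCounts), 1)
    expect_equal(unname(cu2$codonCounts["ATG"]), 1)
    # codons containing N are ambiguous, not counted
    cu3 <- codonUsage("ATGANT")
    expect_equal(cu3$ambiguous, 1)
    # class fractions sum to one over sense codons
    set.seed(4)
    s <- paste(sample(c("A", "C", "G", "T"), 3 * 50, TRUE), collapse = "")
    expect_equal(sum(codonUsage(s)$classFractions), 1)
    expect_error(codonUsage("AT"), "3 bp")
})

test_that("reverse-strand CDS extraction round-trips codon counts", {
    set.seed(5)
    fwd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    contigs <- Biostrings::DNAStringSet(c(
        plus = fwd,
        minus = as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(fwd)))))
    cdsTab <- data.frame(contig_id = c("plus", "minus"),
                         start = c(10, 1), end = c(240, 300 - 9),
                         strand = c("+", "-"))
    cds <- cdsSequences(contigs, cdsTab)
    expect_identical(as.character(cds[[1]])[1],
                     substr(fwd, 10, 240))
    # the minus-strand record covers the same genomic span reversed
    expect_identical(as.character(cds[[2]]), substr(fwd, 10, 300))
    expect_error(cdsSequences(contigs,
        data.frame(contig_id = "plus", start = 0, end = 5, strand = "+")),
        "coordinates")
})

test_that("stop-codon frequencies tally terminal triplets", {
    sc <- stopCodonFrequencies(c("ATGTGA", "ATGTGA", "ATGTAA", "ATGTAG"))
    expect_equal(unname(sc$percent), c(25.0, 25.0, 50.0))  # TAA TAG TGA
    expect_equal(sum(sc$percent), 100)
    one <- stopCodonFrequencies("ATGTGA")
    expect_equal(unname(one$percent["TGA"]), 100.0)
    expect_error(stopCodonFrequencies("ATGTGG"), "not a stop codon")
})

test_that("CDS accounting reconciles multiplicities and completeness", {
    tab <- data.frame(
        contig_id = c("c1", "c2", "c2", "c3", "c4"),
        start = c(1, 1, 400, 1, 1),
        end = c(300, 300, 700, 90, 150),
        hasStart = c(TRUE, TRUE, FALSE, FALSE, FALSE),
        hasStop = c(TRUE, FALSE, TRUE, FALSE, FALSE))
    acc <- cdsAccounting(tab)
    expect_equal(acc$contigsByMultiplicity, c(`1` = 3L, `2` = 1L))
    expect_equal(unname(acc$completeness),
                 c(1L, 1L, 1L, 2L))  # full, startOnly, stopOnly, neither
    expect_equal(acc$totalCds, 5L)
    expect_equal(unname(acc$meanLength["neither"]), mean(c(90, 150)))
    empty <- cdsAccounting(tab[0, ])
    expect_equal(empty$totalCds, 0L)
    expect_equal(sum(empty$completeness), 0L)
})
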
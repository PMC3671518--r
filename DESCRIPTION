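Package: AnagenSeq
Title: Differential Expression and Sequence Analysis of Anagen Skin
    Transcriptomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling de novo assembled skin transcriptomes
    across hair-growth (anagen) libraries: the Audic-Claverie exact test
    for count differences between two RNA-Seq libraries with
    Benjamini-Hochberg correction, RPKM quantification with dual
    q-value/fold-change differential-expression calling, cross-comparison
    (Venn) consistency analysis, hypergeometric functional-category
    enrichment with Bonferroni correction, perfect microsatellite (SSR)
    scanning with motif canonicalization, assembly and coding-sequence
    descriptive statistics (N50, length distribution, GC, codon usage,
    stop-codon frequencies), and 2^-ddCt qPCR concordance. A seeded
    synthetic-data generator produces every input with known ground truth
    so the whole pipeline can be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, Sequencing,
    GeneExpression, Software
RoxygenNote: 7.3.3
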
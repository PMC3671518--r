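#' Run the full anagen-skin profiling pipeline
#'
#' Chains every analysis stage over one set of inputs: RPKM quantification,
#' the Audic-Claverie test with Benjamini-Hochberg correction and dual
#' q-value/fold-change DEG calling for each pairwise comparison against the
#' reference library, cross-comparison consistency, functional-category
#' enrichment of the consistent DEG set, contig/SSR sequence statistics,
#' and qPCR concordance where a Ct table is given. All tables are written
#' tab-separated under `outDir` with a `#` header comment echoing the
#' thresholds; a `run_log.tsv` records per-stage record counts and a
#' `summary.json` the headline numbers. Reruns on identical inputs are
#' byte-identical apart from nothing: no timestamps are written.
#'
#' @param counts a \linkS4class{ContigCountSet}.
#' @param contigs optional named [Biostrings::DNAStringSet]; enables the
#'   sequence-statistics and SSR stages.
#' @param annotation optional annotation data frame (see
#'   [readCategoryTable()]); enables enrichment.
#' @param ct optional Ct table (see [readCtTable()]); enables the qPCR
#'   stage. Its target genes are matched against the consistent DEG calls.
#' @param reference reference library name (sample one of every
#'   comparison); defaults to the first column.
#' @param qThreshold,fcThreshold DEG criteria (defaults 1e-3 and 2).
#' @param ctReferenceGene normaliser gene id in `ct` (default `"REFG"`).
#' @param outDir output directory, created if needed; `NULL` skips all
#'   file output.
#' @return list with `degCalls` (per comparison), `venn`, `enrichment`,
#'   `seqStats`, `ssr`, `qpcr` and `log` (data frame of stage record
#'   counts).
#' @examples
#' sim <- simulateStudy(SimParams(nContigs = 150, seed = 11, deFold = 8,
#'     libraryDepths = c(BL = 1e5, BK = 1e5, BS = 1e5)))
#' res <- runPipeline(sim$counts, contigs = sim$contigs,
#'     annotation = sim$annotation, ct = sim$ct, outDir = NULL)
#' res$venn$totalConsistent
#' @export
runPipeline <- function(counts, contigs = NULL, annotation = NULL,
                        ct = NULL, reference = colnames(counts)[1L],
                        qThreshold = 1e-3, fcThreshold = 2,
                        ctReferenceGene = "REFG", outDir = NULL) {
    stopifnot(is(counts, "ContigCountSet"))
    if (!reference %in% colnames(counts))
        stop("reference library '", reference,
             "' is not in the count table")
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    logRows <- list()
    note <- function(stage, n) logRows[[length(logRows) + 1L]] <<-
        data.frame(stage = stage, records = n)
    hdr <- sprintf("qThreshold=%g fcThreshold=%g reference=%s",
                   qThreshold, fcThreshold, reference)
    emit <- function(df, name) {
        if (is.null(outDir)) return(invisible(NULL))
        p <- file.path(outDir, name)
        con <- file(p, "w"); on.exit(close(con))
        writeLines(paste0("# ", hdr), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }

    others <- setdiff(colnames(counts), reference)
    degCalls <- lapply(others, function(s) {
        calls <- callDEGs(counts, c(reference, s),
                          qThreshold = qThreshold,
                          fcThreshold = fcThreshold)
        note(paste0("deg:", S4Vectors::metadata(calls)$label),
             sum(calls$significant))
        emit(data.frame(contig_id = rownames(calls),
                        as.data.frame(calls)),
             paste0("deg_", S4Vectors::metadata(calls)$label, ".tsv"))
        calls
    })
    names(degCalls) <- paste0(reference, "_vs_", others)

    venn <- NULL
    if (length(degCalls) >= 2L) {
        venn <- consistentDEGs(degCalls[[1L]], degCalls[[2L]])
        note("venn", venn$totalConsistent)
        emit(data.frame(
            set = c(rep("consistent_up", venn$nConsistentUp),
                    rep("consistent_down", venn$nConsistentDown)),
            contig_id = c(venn$consistentUp, venn$consistentDown)),
            "venn_consistent.tsv")
    }

    enrichment <- NULL
    if (!is.null(annotation)) {
        degIds <- if (!is.null(venn))
            c(venn$consistentUp, venn$consistentDown)
        else rownames(degCalls[[1L]])[degCalls[[1L]]$significant]
        enrichment <- enrichCategories(degIds, annotation,
                                       rownames(counts),
                                       qThreshold = qThreshold)
        note("enrichment", sum(enrichment$significant))
        emit(as.data.frame(enrichment), "enrichment.tsv")
    }

    seqStats <- ssr <- NULL
    if (!is.null(contigs)) {
        len <- Biostrings::width(contigs)
        seqStats <- list(n = length(contigs), totalBp = sum(len),
                         meanLength = mean(len), n50 = n50(len),
                         gcPooled = gcContent(contigs, pooled = TRUE),
                         lengthDistribution = lengthDistribution(len))
        note("seqstats", length(contigs))
        hits <- findSSRs(contigs)
        ssr <- list(hits = hits, summary = ssrSummary(hits, contigs))
        note("ssr", length(hits))
        if (!is.null(outDir)) {
            emit(as.data.frame(hits), "ssr_hits.tsv")
            jsonlite::write_json(
                list(seqStats = seqStats[c("n", "totalBp", "meanLength",
                                           "n50", "gcPooled")],
                     ssr = ssr$summary[c("totalSSRs", "contigsWithSSR",
                                         "occurrenceFrequency",
                                         "meanDistanceKb")]),
                file.path(outDir, "summary.json"), auto_unbox = TRUE,
                digits = NA)
        }
    }

    qpcr <- NULL
    if (!is.null(ct)) {
        samples <- unique(ct$sample)
        genes <- setdiff(unique(ct$gene), ctReferenceGene)
        keys <- folds <- pipeFolds <- character(0)
        folds <- pipeFolds <- numeric(0)
        for (s in setdiff(samples, reference)) {
            cmp <- paste0(reference, "_vs_", s)
            if (!cmp %in% names(degCalls)) next
            calls <- degCalls[[cmp]]
            for (g in intersect(genes, rownames(calls))) {
                keys <- c(keys, paste(g, cmp, sep = ":"))
                folds <- c(folds, ddctFoldChange(
                    ct, g, ctReferenceGene, sample = s,
                    calibrator = reference))
                pipeFolds <- c(pipeFolds, calls[g, "foldChange"])
            }
        }
        if (length(keys)) {
            names(folds) <- names(pipeFolds) <- keys
            qpcr <- list(folds = folds, pipelineFolds = pipeFolds,
                         concordance = qpcrConcordance(folds, pipeFolds))
            note("qpcr", length(keys))
            emit(data.frame(key = keys, qpcrFold = folds,
                            pipelineFold = pipeFolds),
                 "qpcr_folds.tsv")
        }
    }

    log <- do.call(rbind, logRows)
    if (!is.null(outDir))
        utils::write.table(log, file.path(outDir, "run_log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    list(degCalls = degCalls, venn = venn, enrichment = enrichment,
         seqStats = seqStats, ssr = ssr, qpcr = qpcr, log = log)
}
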
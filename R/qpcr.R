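#' Relative expression fold change by the 2^-ddCt method
#'
#' Classic relative quantification: per sample, the target gene's mean Ct
#' is normalised against the reference gene (dCt = Ct_target - Ct_ref);
#' the calibrator sample's dCt is subtracted (ddCt); assuming perfect
#' doubling per cycle the fold change of `sample` relative to `calibrator`
#' is 2^-ddCt. Replicate Ct values are aggregated by arithmetic mean.
#'
#' @param ct data frame with columns `gene`, `sample`, `ct` (one row per
#'   technical replicate; a `replicate` column is allowed and ignored).
#' @param target target gene id.
#' @param reference reference (normaliser) gene id.
#' @param sample sample id to quantify.
#' @param calibrator sample id used as the calibrator (fold = 1 there).
#' @return the fold change 2^-ddCt (numeric scalar).
#' @examples
#' ct <- data.frame(gene = rep(c("g", "ref"), each = 2),
#'                  sample = rep(c("A", "B"), 2),
#'                  ct = c(20, 22, 15, 15))
#' ddctFoldChange(ct, "g", "ref", sample = "B", calibrator = "A")  # 0.25
#' @export
ddctFoldChange <- function(ct, target, reference, sample, calibrator) {
    if (!all(c("gene", "sample", "ct") %in% names(ct)))
        stop("'ct' needs columns gene, sample, ct")
    if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
        stop("Ct values must be positive and finite")
    meanCt <- function(g, s) {
        v <- ct$ct[ct$gene == g & ct$sample == s]
        if (length(v) == 0L)
            stop("no Ct values for gene '", g, "' in sample '", s, "'")
        mean(v)
    }
    dCt <- meanCt(target, sample) - meanCt(reference, sample)
    dCtCal <- meanCt(target, calibrator) - meanCt(reference, calibrator)
    2^-(dCt - dCtCal)
}

#' Direction concordance between qPCR and sequencing fold changes
#'
#' Fraction of shared genes whose qPCR fold change and pipeline
#' (RNA-Seq-derived) fold change fall on the same side of 1. Folds exactly
#' equal to 1 agree with either direction; they are counted as agreements
#' and reported separately as ties.
#'
#' @param qpcrFolds,pipelineFolds named numeric vectors of fold changes;
#'   names are matched (e.g. "gene:comparison" keys).
#' @return list with `agreement` (fraction in [0, 1]), `n` genes compared,
#'   `ties`, and `disagreements` (the discordant names).
#' @examples
#' qpcrConcordance(c(g1 = 0.5, g2 = 3), c(g1 = 0.3, g2 = 2.5))$agreement
#' @export
qpcrConcordance <- function(qpcrFolds, pipelineFolds) {
    shared <- intersect(names(qpcrFolds), names(pipelineFolds))
    if (length(shared) == 0L)
        stop("no shared keys between qPCR and pipeline fold changes")
    a <- qpcrFolds[shared]; b <- pipelineFolds[shared]
    tie <- a == 1 | b == 1
    agree <- tie | (a > 1 & b > 1) | (a < 1 & b < 1)
    list(agreement = mean(agree), n = length(shared),
         ties = sum(tie), disagreements = shared[!agree])
}
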
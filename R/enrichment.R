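#' Hypergeometric upper-tail probability for category over-representation
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` annotated DEGs
#' without replacement from an annotated background of `N` contigs of which
#' `K` belong to the category, the probability of seeing `k` or more
#' category members. The tail is inclusive of `k` (the standard
#' over-representation convention) and exact (`stats::phyper`).
#'
#' @param k observed DEGs in the category.
#' @param K background contigs in the category.
#' @param n annotated DEGs drawn.
#' @param N annotated background size.
#' @return probability in (0, 1].
#' @examples
#' hypergeomTail(4, K = 5, n = 4, N = 10)   # 5/210
#' @export
hypergeomTail <- function(k, K, n, N) {
    bad <- is.na(k) | is.na(K) | is.na(n) | is.na(N) |
        k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(n, K)
    if (any(bad))
        stop("inconsistent hypergeometric margins: need 0 <= k <= min(n, K),",
             " K <= N, n <= N")
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Functional-category over-representation of a DEG set
#'
#' Tests each functional category (e.g. a KOG cluster) for
#' over-representation among differentially expressed contigs relative to
#' the annotated transcriptome background, using the hypergeometric
#' upper-tail test with Bonferroni correction. Only annotated contigs enter
#' the universe: unannotated contigs are excluded from both `n` and `N`,
#' matching how enrichment margins are reported against an annotated
#' background. A contig carrying several categories counts once in each.
#'
#' @param degIds character vector of DEG contig ids (must be a subset of
#'   `backgroundIds`).
#' @param annotation data frame with columns `contig_id` and `categories`
#'   (comma-separated category ids), or a named list of category id vectors.
#' @param backgroundIds character vector of all contig ids in the
#'   transcriptome background.
#' @param qThreshold significance threshold on the Bonferroni-corrected
#'   q-value (default 1e-3).
#' @return a [S4Vectors::DataFrame] with one row per category present in
#'   the annotated background: `category`, `k`, `n`, `K`, `N`, `pValue`,
#'   `qValue` (= min(1, p * categories tested)) and `significant`, sorted
#'   by p-value.
#' @examples
#' ann <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
#'                   categories = c("A", "A", "B", "B"))
#' enrichCategories(c("c1", "c2"), ann, paste0("c", 1:6))
#' @export
enrichCategories <- function(degIds, annotation, backgroundIds,
                             qThreshold = 1e-3) {
    if (!all(degIds %in% backgroundIds))
        stop("degIds must be a subset of backgroundIds")
    catList <- .asCategoryList(annotation)
    catList <- catList[names(catList) %in% backgroundIds]
    if (length(catList) == 0L)
        stop("empty annotated background: no background contig carries an",
             " annotation")
    annBg <- names(catList)
    annDeg <- intersect(degIds, annBg)
    N <- length(annBg)
    n <- length(annDeg)
    cats <- sort(unique(unlist(catList, use.names = FALSE)))
    inCat <- lapply(cats, function(cc)
        annBg[vapply(catList, function(v) cc %in% v, logical(1))])
    K <- lengths(inCat)
    k <- vapply(inCat, function(ids) length(intersect(ids, annDeg)),
                integer(1))
    p <- hypergeomTail(k, K, n, N)
    q <- stats::p.adjust(p, method = "bonferroni")
    res <- S4Vectors::DataFrame(
        category = cats, k = k, n = n, K = K, N = N,
        pValue = p, qValue = q, significant = q < qThreshold)
    res <- res[order(res$pValue, res$category), ]
    S4Vectors::metadata(res) <- list(qThreshold = qThreshold,
                                     nCategoriesTested = length(cats))
    res
}

.asCategoryList <- function(annotation) {
    if (is.list(annotation) && !is.data.frame(annotation)) {
        if (is.null(names(annotation)))
            stop("a list annotation must be named by contig id")
        return(lapply(annotation, as.character))
    }
    if (!all(c("contig_id", "categories") %in% names(annotation)))
        stop("'annotation' needs columns 'contig_id' and 'categories'")
    out <- lapply(strsplit(as.character(annotation$categories), ","),
                  trimws)
    names(out) <- annotation$contig_id
    out[lengths(out) > 0L & vapply(out, function(v) all(nzchar(v)),
                                   logical(1))]
}
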
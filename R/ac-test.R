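#' Audic-Claverie point probability for two library counts
#'
#' Exact probability p(y | x) of observing `y` reads for a contig in sample
#' two given `x` reads in sample one, when both libraries sample the same
#' underlying transcript population with total uniquely mapped reads `N1`
#' and `N2`:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#' This is the negative-binomial mass with `x + 1` successes and success
#' probability `N1 / (N1 + N2)` evaluated at `y`; it is computed in
#' log-space via `lgamma` so it stays finite for counts into the millions.
#'
#' @param x,y non-negative integer read counts (vectorised, recycled).
#' @param N1,N2 positive totals of uniquely mapped reads in samples one and
#'   two.
#' @return numeric vector of probabilities in (0, 1].
#' @seealso [acPValue()] for the two-sided test, [callDEGs()] for the full
#'   differential-expression caller.
#' @examples
#' acPointProb(0, 0, 1e6, 1e6)   # 0.5
#' acPointProb(5, 5, 1e6, 1e6)   # choose(10, 5) / 2^11
#' @export
acPointProb <- function(x, y, N1, N2) {
    .checkAcInput(x, y, N1, N2)
    r <- N2 / N1
    exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

.checkAcInput <- function(x, y, N1, N2) {
    if (any(is.na(x)) || any(is.na(y)) || any(x < 0) || any(y < 0) ||
        any(x != round(x)) || any(y != round(y)))
        stop("'x' and 'y' must be non-negative integer counts")
    if (any(is.na(c(N1, N2))) || any(N1 <= 0) || any(N2 <= 0))
        stop("library totals N1 and N2 must be positive")
    invisible(TRUE)
}

#' Two-sided Audic-Claverie p-value
#'
#' Forms a two-sided significance value from the Audic-Claverie point
#' probability: in each of the two sample orientations the one-sided tail in
#' the direction of the observed deviation (inclusive of the observed count)
#' is evaluated through the negative-binomial cumulative (regularised
#' incomplete beta, so no O(y) summation); the smaller orientation tail is
#' doubled and capped at 1. Taking the minimum over both orientations makes
#' the value exactly symmetric under swapping (x, N1) with (y, N2).
#'
#' @inheritParams acPointProb
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' acPValue(10, 0, 1e6, 1e6)   # 2 / 2^11
#' acPValue(5, 5, 1e6, 1e6)    # 1: y sits at its conditional expectation
#' @export
acPValue <- function(x, y, N1, N2) {
    .checkAcInput(x, y, N1, N2)
    n <- max(length(x), length(y))
    x <- rep_len(x, n); y <- rep_len(y, n)
    p1 <- N1 / (N1 + N2)        # success prob, orientation 1 (y random)
    p2 <- N2 / (N1 + N2)        # orientation 2 (x random)
    lowerA <- stats::pnbinom(y, size = x + 1, prob = p1)
    upperA <- stats::pnbinom(y - 1, size = x + 1, prob = p1,
                             lower.tail = FALSE)
    lowerB <- stats::pnbinom(x, size = y + 1, prob = p2)
    upperB <- stats::pnbinom(x - 1, size = y + 1, prob = p2,
                             lower.tail = FALSE)
    tail <- pmin(pmin(lowerA, upperA), pmin(lowerB, upperB))
    # tails beyond double precision underflow to 0; clamp so p stays in (0, 1]
    tail <- pmax(tail, .Machine$double.xmin)
    pmin(1, 2 * tail)
}

#' Benjamini-Hochberg adjustment of Audic-Claverie p-values
#'
#' Validated wrapper over the standard step-up false-discovery-rate
#' procedure (`stats::p.adjust(method = "BH")`). Input order is preserved;
#' every adjusted value is >= its raw value and <= 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
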
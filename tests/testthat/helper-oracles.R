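# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (enumeration, per-position
# brute force, direct summation) so agreement is informative.

# N50 straight from the definition: the largest L such that contigs of
# length >= L hold at least half the total length (O(n^2) scan).
n50Oracle <- function(lengths) {
    total <- sum(lengths)
    ok <- vapply(sort(unique(lengths), decreasing = TRUE),
                 function(L) sum(lengths[lengths >= L]) >= total / 2,
                 logical(1))
    sort(unique(lengths), decreasing = TRUE)[ok][1]
}

# Hypergeometric upper tail by direct enumeration of choose() ratios.
hypergeomOracle <- function(k, K, n, N) {
    js <- k:min(n, K)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Brute-force SSR detection: at every start position and every unit size,
# count full motif copies by direct substring comparison; keep primitive
# motifs with >= 2 copies spanning >= minLen bp; resolve overlaps by span
# length, then start, then unit size (the published resolution order).
ssrOracle <- function(seq, minLen = 18L, units = 2:6) {
    n <- nchar(seq)
    isPrim <- function(m) {
        u <- nchar(m)
        for (d in seq_len(u - 1L))
            if (u %% d == 0L &&
                identical(strrep(substr(m, 1, d), u / d), m))
                return(FALSE)
        TRUE
    }
    cand <- list()
    for (u in units) {
        for (i in seq_len(max(0L, n - 2L * u + 1L))) {
            motif <- substr(seq, i, i + u - 1L)
            if (grepl("[^ACGT]", motif)) next
            k <- 1L
            while (i + (k + 1L) * u - 1L <= n &&
                   substr(seq, i + k * u, i + (k + 1L) * u - 1L) == motif)
                k <- k + 1L
            if (k >= 2L && k * u >= minLen && isPrim(motif))
                cand[[length(cand) + 1L]] <- data.frame(
                    start = i, end = i + k * u - 1L, motif = motif,
                    repeats = k, unit = u)
        }
    }
    if (!length(cand))
        return(data.frame(start = integer(0), end = integer(0),
                          motif = character(0), repeats = integer(0)))
    cand <- do.call(rbind, cand)
    cand <- cand[order(-(cand$end - cand$start + 1L), cand$start,
                       cand$unit), ]
    kept <- cand[0, ]
    for (i in seq_len(nrow(cand)))
        if (!nrow(kept) || all(cand$start[i] > kept$end |
                               cand$end[i] < kept$start))
            kept <- rbind(kept, cand[i, ])
    kept <- kept[order(kept$start), c("start", "end", "motif", "repeats")]
    rownames(kept) <- NULL
    kept
}

# Repeat-rich random sequence: uniform background with a few planted
# tandem repeats of random primitive motifs straddling the 18 bp floor, so
# oracle comparisons exercise hits, near-misses and conflicts.
randomSSRSeq <- function(len = 1000L, nPlants = 3L) {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    for (i in seq_len(nPlants)) {
        u <- sample(2:6, 1L)
        motif <- paste(sample(c("A", "C", "G", "T"), u, TRUE),
                       collapse = "")
        reps <- sample(2:12, 1L)
        span <- u * reps
        if (span > len) next
        at <- sample.int(len - span + 1L, 1L)
        substr(s, at, at + span - 1L) <- strrep(motif, reps)
    }
    s
}
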
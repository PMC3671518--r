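---
title: "Methods: count-based differential expression and sequence analysis of anagen skin transcriptomes"
author: "AnagenSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-based differential expression and sequence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AnagenSeq)
```

# Scope and data model

AnagenSeq re-implements, as a tested and reusable library, the statistical
core of a classic single-replicate RNA-Seq comparison across skin types of
the cashmere goat during the active hair-growth (anagen) phase: three
sequencing libraries (belly `BL`, back `BK`, body side `BS`), one per skin
type, mapped against a de novo assembled contig catalogue. The central
container is `ContigCountSet`, a `SummarizedExperiment` holding the
contigs x libraries matrix of uniquely mapped read counts, per-contig
lengths in `rowData()`, and per-library totals \(N_s\) in `colData()`.
Sequences travel as `Biostrings::DNAStringSet`, SSR hits as
`GenomicRanges::GRanges`.

Because the original raw data (130 million reads, an assembler, external
annotation databases) are far beyond a package check, every input can be
generated synthetically with known ground truth (`simulateStudy()`); the
package's claims are validated against that truth and against the
arithmetic worked examples a published study report prints.

# The exact test for a count difference between two libraries

For a contig with \(x\) reads in sample one (total \(N_1\)) and \(y\) in
sample two (total \(N_2\)), the conditional probability that the same
underlying transcript abundance produced \(y\) is

\[
p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\bigl(1+N_2/N_1\bigr)^{x+y+1}},
\]

the posterior predictive of a Poisson count under a flat prior on the
rate. `acPointProb()` evaluates it in log-space through `lgamma`, so it is
finite and positive up to counts of \(10^7\). The mass is exactly the
negative-binomial distribution with \(x+1\) successes and success
probability \(N_1/(N_1+N_2)\); the test suite verifies both the
normalisation \(\sum_y p(y\mid x) = 1\) (to \(10^{-10}\)) and agreement
with an independently computed negative-binomial mass.

## From point probability to a two-sided p-value

A point probability is not a test; a sidedness convention is needed.
`acPValue()` forms, in each of the two sample orientations, the one-sided
tail in the direction of the observed deviation from the conditional
expectation, inclusive of the observed count, evaluated through the
negative-binomial cumulative (the regularised incomplete beta, so no
\(O(y)\) summation is ever done). The smaller of the orientation tails is
doubled and capped at 1.

Two details deserve a note:

* **Symmetry.** The doubled inclusive tail of a *single* orientation is
  not exactly invariant under swapping \((x, N_1)\) with \((y, N_2)\): the
  two orientations' tails differ by a boundary point-mass term (at
  \(x{=}10, y{=}0, N_1{=}N_2\) they are \(2^{-11}\) and \(2^{-10}\)).
  Taking the minimum over both orientations restores exact label symmetry
  while leaving textbook worked values unchanged (that example gives
  \(2/2^{11} \approx 9.77\times10^{-4}\)).
* **Conservatism.** Doubling an inclusive discrete tail is conservative:
  for weakly covered contigs the attainable p-values are coarse, and the
  realised null rejection fraction at \(\alpha = 0.05\) sits slightly
  below \(\alpha\) (around 0.044-0.049 under the default synthetic null
  of 10,000 Poisson contigs at two million reads per library). This is a
  property of exact discrete tests, not an implementation artefact; the
  suite checks the rejection rate against a 99% binomial band around
  \(\alpha\), a check that is intentionally strict and sits at the edge
  of what a conservative exact test can meet.
* **Underflow.** Tails smaller than the smallest positive double are
  clamped to it so that downstream adjustment never sees a literal zero.

Multiple testing is corrected with the Benjamini-Hochberg step-up rule
(`bhAdjust()`, a validated wrapper over `stats::p.adjust`). The original
study's description of its correction procedure is ambiguous; BH is the
standard choice for q-value-style false-discovery-rate control and is
exposed as an option in `callDEGs()`.

# RPKM and the dual DEG criterion

Expression is quantified as reads per kilobase per million mapped reads,
\(\mathrm{RPKM} = 10^9 C / (N_s L)\). A contig is called differentially
expressed in a pairwise comparison when **both** criteria hold:

* adjusted \(q < 10^{-3}\) (threshold `qThreshold`), and
* an RPKM ratio of at least 2-fold in either direction, inclusive
  (`fcThreshold = 2`; "at least 2-fold" includes exactly 2).

Ratios are undefined when the reference count is zero, so the fold
criterion uses a pseudocount-stabilised ratio,
\(((y+1)/N_2) \big/ ((x+1)/N_1)\) — contig length cancels. The reported
RPKM columns stay unmodified; only the criterion uses the stabilised
value. This keeps all-zero contigs non-significant without discarding
presence/absence cases. "Up" always means higher in sample two; fixing
sample one to the reference library (`BL`) reproduces the reference
orientation of a three-skin-type design.

`consistentDEGs()` intersects the up- and down-sets of two comparisons
sharing the reference, the Venn-diagram notion of contigs consistently
regulated in both cashmere-producing skin types relative to belly skin.

# Category enrichment

`enrichCategories()` tests each functional category (KOG-style cluster)
for over-representation among DEGs with the hypergeometric upper tail
\(P(X \ge k)\) (inclusive, `stats::phyper`), Bonferroni-corrected across
the categories tested, significant at \(q < 10^{-3}\). The universe is
**annotated contigs only**: contigs without any category are excluded
from both the background \(N\) and the DEG draw \(n\), matching how
enrichment margins are conventionally reported against an annotated
background. A contig with several categories counts once in each.

# Sequence statistics

* `lengthDistribution()` uses the inclusive report bins 301-500, 501-700,
  701-1000, 1001-1500, 1501-2000, >2000 bp. Published tables sometimes
  print an overlapping "1500 ~ 2000" boundary; the package resolves it as
  1501-2000 so the bins partition and counts always sum to the input
  size.
* `n50()` is the largest length L such that contigs of length >= L cover
  at least half the assembly.
* `codonUsage()` reads in-frame codons from position 1 of each CDS
  (trailing bases ignored, N-containing codons tallied as ambiguous) and
  summarises amino-acid classes over sense codons with the standard
  genetic code. The class partition is the standard 10/5/2/3 split:
  nonpolar G, A, V, L, I, P, F, M, W, C; polar uncharged S, T, Y, N, Q;
  acidic D, E; basic K, R, H.
* `stopCodonFrequencies()` tallies terminal TAA/TAG/TGA of
  stop-containing CDSs; a non-stop terminal triplet is a validation
  error, not a silent skip.
* `cdsAccounting()` reconciles three views of a CDS annotation — contig
  multiplicity, completeness classes (full / start-only / stop-only /
  neither), and the record count — into one total.
* Coordinates are 1-based inclusive everywhere in I/O;
  `cdsSequences()` reverse-complements minus-strand records.

# SSR scanning

An SSR is a perfect tandem repeat of a primitive 2-6 bp motif whose
full-copy span reaches 18 bp. `findSSRs()` locates maximal period-u
regions by comparing the sequence with itself shifted by u; every anchor
inside a region is a candidate whose span covers the full motif copies
reachable from it. Conflicts (phases, nested unit sizes, abutting
regions) are resolved deterministically: longest span first, then
left-most, then shortest unit; hits never overlap. Partial trailing
copies extend neither the span nor the count; `N` breaks runs;
non-primitive motifs are never reported (a \((AT)_{10}\) run is AT, not
ATAT). `canonicalMotif()` folds rotation and reverse complement to the
lexicographic minimum, so GT, TG, CA and AC all report as AC.

One consequence of maximality worth knowing: if random flanking sequence
happens to extend a repeat, the reported span can be phase-shifted by up
to one unit relative to where a repeat was deliberately written. The
planted-recovery tests are therefore phase-tolerant (same locus, same
canonical class, span at least as long); the brute-force oracle
comparison is exact.

`ssrSummary()` reports occurrence frequency (SSRs per 100 contigs) and
mean inter-SSR spacing (assembly bp per SSR); with zero hits the spacing
is undefined and reported `NA`.

# qPCR concordance

`ddctFoldChange()` implements relative quantification under the assumed
doubling-per-cycle efficiency: replicate Ct values are averaged
arithmetically, \(\Delta Ct\) normalises the target against a
user-chosen reference gene (never hard-coded), \(\Delta\Delta Ct\)
subtracts the calibrator sample, and the fold is \(2^{-\Delta\Delta
Ct}\). `qpcrConcordance()` scores the fraction of genes whose qPCR and
sequencing folds fall on the same side of 1; folds exactly 1 agree with
either side and are reported separately as ties.

# The synthetic-data generator

`simulateStudy()` produces every pipeline input with known truth. Its
defaults are fixed study conditions, not tuning knobs:

* **Contig lengths**: log-normal truncated at 301 bp with
  meanlog \(-2.88\), sdlog \(2.77\) (inverse-CDF sampling, since the
  truncation discards most of the untruncated mass). These values were
  calibrated once against a published goat skin assembly summary — mean
  length ~924 bp, N50 ~1380 bp, ~46% of contigs in 301-500 bp — and give
  mean ~970 bp, N50 ~1360 bp at 49,115 contigs.
* **Base composition**: i.i.d. bases at GC 0.549, the reported average of
  that transcriptome's coding regions. The generator does not emulate
  codon structure, isochores or k-mer correlations; sequence-statistics
  tests that depend only on composition and planted repeats are
  unaffected, but nothing here validates behaviour on real coding
  sequence bias.
* **Expression levels**: log-normal with sdlog 1.5, reproducing the
  several-orders-of-magnitude per-contig coverage range of deep skin
  transcriptomes (a reported 2- to 164,789-fold depth range implies a
  log-sd near 1.4-1.5 over ~50,000 contigs).
* **Library depths**: two million uniquely mapped reads per library by
  default (the scale at which the recovery properties are stated);
  recorded totals are always the realised column sums, so count
  conservation holds exactly.
* **Planted differential expression**: a `deFraction` of contigs at fold
  `deFold`, half up, half down, applied consistently in every
  non-reference library. Down-regulation is planted as elevated
  expression in the *reference* library: relative folds are identical,
  but the balanced design keeps expected library totals comparable, as in
  real compositional mRNA pools. The naive multiply-here/divide-there
  design inflates treatment totals by tens of percent at large folds,
  which — in a pipeline whose only normalisation is by total mapped reads
  (TMM-style corrections are out of scope) — shifts every null contig's
  expected ratio and manufactures false discoveries that say nothing
  about the test itself.
* **Counts**: Poisson around the per-library means (`dispersion = 0`,
  the regime in which the exact test's model is correct), or gamma-mixed
  negative binomial for `dispersion > 0` to probe anticonservatism under
  overdispersion. Real single-replicate libraries carry unknown
  overdispersion; the Poisson default is the test-consistent limit, and
  results at `dispersion > 0` quantify how fragile the calibration is,
  not what any real pair of libraries does.
* **Categories**: a configurable annotated fraction (~36%, mirroring how
  sparse real category annotation is), one to two categories per
  annotated contig, with the odds of category `C01` multiplied by
  `enrichedCategoryEffect` for DE contigs. Effect 1 is an exact null.
* **qPCR**: replicate Ct values with
  \(Ct_\text{target}-Ct_\text{ref} = \delta_g - \log_2(\text{fold})\)
  plus Gaussian noise (sd 0.1, three replicates by default); the
  reference gene is flat across samples by construction.

All generators derive their random streams deterministically from the
single integer seed, so identical `SimParams` give bit-identical FASTA
bytes, count matrices and Ct tables.

## What the synthetic validation does and does not show

Passing tests demonstrate: the exact test's internal consistency and
calibration under its own model; recovery of planted effects at stated
sizes (fold 8, depth 2 x 10^6, 5,000 contigs: sensitivity >= 0.99 with
false-discovery proportion <= 0.01 in measured runs); exact agreement of
the SSR scanner, N50, binning and enrichment with brute-force oracles;
and exact reproduction of report arithmetic from printed inputs. They do
not demonstrate robustness to biological replication variance (the
design has one library per skin type), mapping ambiguity, assembly
artefacts, or annotation bias — none of which the generator models.

# Problem sizes and numerical choices

The suite runs its statistical checks at 10,000 contigs (null
calibration), 5,000 contigs (recovery), 500 random kilobase sequences
(SSR oracle), complete margin enumeration up to N = 25 (enrichment), and
40-200 seeded repetitions for rate-style properties; these sizes were
chosen so each property's Monte-Carlo error is well below the margin it
is tested against. Tolerances: normalisation to \(10^{-10}\);
oracle-agreement checks to \(10^{-12}\); everything stochastic against
pre-stated bands. Degenerate inputs fail loudly (zero library totals,
empty assemblies, non-stop terminal codons, inconsistent hypergeometric
margins, plants that do not fit) rather than returning silent defaults;
the one deliberate `NA` is the mean inter-SSR distance of a hit-free
assembly.

# Known limitations

* One library per condition: no replicate-aware inference (negative
  binomial GLMs are explicitly out of scope).
* Normalisation is total-count (RPKM) only; composition bias between
  libraries is not corrected.
* The SSR scanner reports perfect repeats only — no compound or
  interrupted microsatellites.
* qPCR efficiency is fixed at 2; no standard-curve correction.
* The enrichment universe is the annotated background; conclusions do
  not extend to unannotated contigs.
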
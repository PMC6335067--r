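---
title: "Methods: binned bisulfite methylome analysis with methylbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned bisulfite methylome analysis with methylbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

methylbin analyses whole-genome bisulfite sequencing (BS-Seq) methylomes in
the three plant cytosine contexts — symmetric CG and CHG (H = A, T or C)
and asymmetric CHH. Its statistical core has three layers.

**Methylcytosine calling.** After bisulfite conversion, an unmethylated
cytosine reads as T; conversion is imperfect, so a truly unmethylated site
still shows unconverted reads at the non-conversion rate *r*, estimated
upstream from an unmethylated lambda spike-in (*r* = 0.006 here, consumed
as an input — the package never re-estimates it). For a site with *m*
unconverted reads out of *n*, `site_pvalue()` computes the exact one-sided
binomial tail `P(X >= m)` for `X ~ Binomial(n, r)`. A site is called
methylated when it is covered by at least 3 reads (inclusive), `p < 1e-5`,
and the methylated ratio `m/n` strictly exceeds 0.25. The direction is
one-sided by design: non-conversion can only inflate apparent methylation,
never deflate it. No multiple-testing correction is applied at the site
level; the fixed `1e-5` threshold is the method's operating point, and
`min_methylated_count()` tabulates what it implies per coverage (3 of 3
reads; 4 of 10).

**Differential methylation.** DMRs are tested in non-overlapping 100-bp
bins. A bin enters testing only if it holds at least 10 *informative*
cytosines of the context — sites covered by more than 3 reads (>= 4) — in
*each* of the two samples. This is the stricter, symmetric reading of the
informative filter; the looser either-sample reading can be emulated by
lowering `min_informative`. The slight mismatch between the caller's
>= 3-read floor and the informative >= 4-read floor is intentional and
kept as two separate parameters. Each tested bin's pooled counts form a
2x2 table tested with a two-sided Fisher's exact test (`fisher_bin_test()`
sums hypergeometric probabilities no larger than the observed table's; an
all-zero margin gives p = 1 by convention). Benjamini-Hochberg adjustment
runs across all tested bins of one context within one pairwise comparison
— never pooled across contexts or comparisons — and bins with q < 0.05 are
DMRs. DMRs are single significant bins, never merged, and no minimum delta
is imposed; `delta = level_b - level_a` is reported so users can
post-filter, and "hyper" always means the second sample is higher. DMCs
are single positions covered >= 3 reads in both samples where the two
binomial call statuses disagree and the absolute level difference reaches
the context threshold (CG 0.7, CHG 0.5, CHH 0.1); a per-site Fisher
variant is available behind `method = "fisher"`.

**Levels and profiles.** The "methylation level" of any site set is the
weighted (pooled-count) level: summed methylated reads over summed reads.
Pooling weights every read equally, which makes the level robust to uneven
coverage; the mean-of-ratios alternative is available everywhere via
`method = "mean"` for sensitivity checks. CG sites on opposite strands are
deliberately *not* merged into symmetric dyads — each strand's cytosine is
an independent site, matching the per-strand cytosine-report convention.
Metagene profiles align features at their TSS and TTS: bodies are rescaled
to 100 fractional bins, while the 2-kb flanks are cut into 100 fixed-width
20-bp bins, so flank distances stay interpretable (a 500-bp CHH island
occupies the 25 upstream-proximal bins regardless of gene length).
Minus-strand features are reversed so bin 1 is always 5'-most. RdDM-locus
profiles use the same contract with 5-kb flanks. Sliding windows let a
cytosine contribute to every window containing it; with step = window the
read-weighted mean of window levels equals the genome-wide level exactly,
a conservation identity the tests assert.

# Coordinates and formats

Internally all intervals are 0-based half-open. Cytosine reports use
1-based positions (the common caller dialect), GFF3 is 1-based inclusive
and BED 0-based half-open; the readers and writers in `methylome_io`
convert at the boundary and reject malformed records (with line numbers)
rather than coercing. Gzip is sniffed from the file extension. Chromosome
scaffolds receive no special-casing: whatever chromosomes appear in a
report are processed, and subgenome summaries simply group by the leading
A/D letter of the chromosome name.

# The synthetic-data generator

Real cotton-scale data (hundreds of millions of cytosines) is not needed
to exercise any of the statistics above, so `sim_config()` +
`simulate_dataset()` generate a miniature study whose *structure* matches
the analyses' assumptions:

- **Genome and annotation** — two 500-kb chromosomes named A01/D01 (the
  allotetraploid subgenome convention), 30 protein-coding genes with 1-4
  exons, 8 TE-related genes and 60 TEs per chromosome, TE lengths spanning
  the short (< 0.5 kb, weight 0.54), medium (0.45) and long (> 4 kb, 0.01)
  classes. Features are placed uniformly at random without overlap;
  placement fails loudly if the request exceeds chromosome capacity.
  Contexts are assigned from the simulated sequence triplets, so context
  proportions are realistic for random sequence but not calibrated to any
  particular genome.
- **Methylation** — per-site true levels are Beta-distributed around
  context means CG 0.75, CHG 0.45, CHH 0.08 (concentration 10; `Inf`
  yields zero-variance levels exactly at the mean, used by degenerate-case
  tests). A CHH island adds 0.15 over the 500 bp immediately upstream of
  each TSS. Each gene additionally draws a promoter-wide CHH baseline from
  Beta(mean 0.25, concentration 2): without between-gene variance in
  promoter methylation the methylation-expression coupling would be
  unidentifiable at any sample size, and this is the one generator
  parameter left fully open by the design, chosen once for
  identifiability.
- **Observation model** — coverage is Poisson(30) by default (a
  negative-binomial switch adds over-dispersion), and the methylated read
  count is `Binomial(n, m + (1 - m) r)` with r = 0.006: non-conversion
  adds false methylation signal but methylated cytosines are never falsely
  converted, mirroring the lambda-control calibration.
- **Planted DMRs** — by default 20 bins per context shifted in the second
  sample by CG -0.8, CHG +0.5, CHH +0.4, each bin guaranteed >= 15
  cytosines of its context so recovery failures indicate caller faults,
  not simulation faults. The CG shift is negative because the CG baseline
  (0.75) leaves no headroom for +0.8; shifts that would leave [0, 1] are
  clamped and flagged, and the realised per-bin deltas are recorded in the
  truth table.
- **siRNA loci and expression** — 300 24-nt siRNA loci (merged-alignment
  lengths 24-96 nt), a fraction 0.8 of them placed inside
  CHH-hypermethylated DMR bins (the RdDM co-location); gene expression
  follows `log2(FPKM + 1) = 6 - 4 * promoter_CHH + N(0, 0.5)`, with the
  slope optionally restricted to a subset of genes. The accompanying
  p-values are a simulation convenience (normal test on the known noise
  sd), not a re-implementation of an RNA-Seq differential test.

Every output stream derives its own sub-seed from the master seed, so
regenerating one file never perturbs the others and a fixed seed makes the
whole pipeline byte-identical — `run_pipeline()` is tested for exactly
that.

What the generator does *not* emulate: linkage between neighbouring sites
(levels are independent given their means), genome-scale repeat structure,
mappability artifacts, strand-coverage asymmetries, or cotton-calibrated
effect-size distributions. Passing tests therefore demonstrate the
*statistical machinery* — calibration of the caller, FDR control,
recovery power, profile correctness — not concordance with any particular
organism's numbers.

# Numerical choices and edge cases

- Fisher two-sided summation uses a `1 + 1e-7` relative tolerance when
  comparing hypergeometric point probabilities, so ties are not broken by
  floating-point noise; the implementation is validated bit-for-bit
  against a log-binomial-coefficient enumeration oracle for all tables
  with margins up to 40.
- Zero-coverage site sets, empty bins, promoters without covered
  cytosines, and profile bins without reads are all *undefined* (`NA`),
  never zero: absence of evidence is distinguished from evidence of
  absence throughout.
- TE length classes are strict at both boundaries (a 4000-bp TE is
  medium, not long; a 500-bp TE is medium, not short).
- k-means clustering (`cluster_expression()`) z-scores each gene across
  stages, then runs Lloyd's algorithm with 10 random restarts under a
  fixed seed, keeping the lowest within-cluster sum of squares; clusters
  are relabelled by descending first-stage centroid (roman numerals I-X),
  a deterministic convention imposed for reproducibility since no natural
  ordering exists. When standardisation collapses profiles onto fewer
  distinct points than k (unavoidable with two stages), k is reduced with
  a warning rather than failing.
- The expression correlation reports both plain Pearson r and the signed
  r-squared `sign(r) * r^2`, because methylome-expression figures in this
  literature conventionally print negative "R^2" values for negative
  couplings.
- The rank-sum comparison of siRNA-overlapped vs non-overlapped genes
  uses `stats::wilcox.test()` semantics: exact for small samples without
  ties, normal approximation with tie correction otherwise.
- The TE up/down balance test is a 1-df goodness-of-fit chi-squared
  against 50:50 without continuity correction.

# Problem sizes used by the tests

The test-suite simulations are sized for quick desk-scale runs while
keeping every asymptotic claim honest: module tests run on a 2 x 100-kb
genome (~100k cytosines); FDR control is checked on a 2 x 2.6-Mb CHH-only
null with 52,000 testable bins; coupling recovery uses 2,000 genes on a
2 x 4.5-Mb genome; caller and Fisher oracles are exhaustive (all counts to
n = 200; all 741,321 tables with margins <= 40). These sizes are the
package's chosen benchmark conditions, large enough that Monte-Carlo error
is far below every asserted tolerance.

# Known limitations

- DMRs are single 100-bp bins; there is no smoothing, HMM segmentation or
  bin merging, by design.
- The non-conversion rate is a trusted input; per-read conversion QC and
  lambda processing are upstream concerns.
- Alignment, transcript quantification and differential-expression testing
  are consumed as finished tables, never recomputed.
- Sharing classification keys on exact `(chrom, pos, strand, context)`
  addresses with no positional fuzz, so it is sensitive to coordinate
  mismatches between reports.
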
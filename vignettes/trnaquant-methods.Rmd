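---
title: "Quantifying mature tRNA expression from small RNA-seq: methods and design"
author: "trnaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mature tRNA expression from small RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transfer RNAs are short (73–90 nt), heavily structured, and encoded by
hundreds of near-identical genomic loci. A small RNA-seq library contains a
mixture of mature tRNAs (introns spliced, flanks trimmed, a
post-transcriptionally added 3' CCA), premature transcripts that still carry
flanking sequence, tRNA-derived fragments, and plain genomic background. A
read aligned naively to the genome cannot distinguish these origins, and
multi-copy loci make per-locus counts ambiguous. `trnaquant` implements a
two-round mapping strategy that separates mature tRNA signal from premature
and non-tRNA reads before counting, and carries the counts through an
edgeR-style two-group differential-expression analysis.

## Reference construction

From a genome FASTA and a tRNAscan-SE tabular annotation the package builds
two references (`build_bundle()`):

* **Artificial genome** — the input chromosomes with every annotated tRNA
  gene span replaced by `N`s, plus one *premature decoy chromosome* per
  gene: the unspliced gene body with up to 50 nt of flanking sequence on
  each side (`flank_len`, truncated at chromosome edges), oriented to the
  gene strand. Each decoy records its upstream flank length and gene length
  so the pure gene-body interval is recoverable.
* **Mature reference** — one record per gene: strand-oriented, introns
  removed, `CCA` appended.

Masking only covers the annotated gene span, not its flanks, so flank
sequence exists both on the masked chromosome and on the decoy. This is
harmless for classification: any read carrying gene-body bases mismatches
the masked copy and is pulled to the decoy.

Intron handling is a deliberate extension: tRNA biogenesis splices introns
out of the mature molecule, so mature records are spliced while decoys keep
the genomic (unspliced) sequence. Consequences are discussed under
*Limitations*.

Genes are named GtRNAdb-style, `tRNA-{isotype}-{anticodon}-{group}-{copy}`:
loci with identical spliced mature sequence share a group (numbered within
each isotype/anticodon family by descending maximum annotation score, ties
by sequence), and copies within a group are ordered by genomic position.
Group numbering by score is a package convention; the database's own
ordering rule is not published. A gene is counted only if it is cytosolic
(its chromosome does not match a mitochondrial naming pattern —
tRNAscan-SE output carries no organelle flag, so chromosome naming is the
only generic signal), high-confidence, and not a pseudogene.

## Read preprocessing

Single-end FASTQ reads are 3'-adapter trimmed and filtered
(`preprocess_fastq()`). The trimmer finds the leftmost position whose read
suffix matches a prefix of the adapter end-anchored, with mismatches at most
`floor(0.1 × overlap)` and overlap at least 3 nt; leftmost (longest
overlap) wins, which guards against adapter read-through. Reads shorter
than `min_len` (default 15 nt — shorter reads cannot place uniquely under a
3-mismatch budget) after trimming are dropped as *too short*; remaining
reads with mean Phred quality below the threshold (25 or 30 by convention)
are dropped as *low quality*. The QC report's partition
`passed + too_short + low_quality = total` holds exactly on every input.
The shipped preset adapter sequences (Illumina small RNA 3',
Illumina universal, SOLiD) are conventional defaults and overridable; the
mean-quality rule is a whole-read filter, chosen because the workflow
reports whole-read removal counts.

## Alignment model

The internal aligner (`align_batch()`) is deliberately minimal: end-to-end,
ungapped, up to `k = 3` mismatches, both strands of every reference, best
hit only — the contract of classic `-v 3 --best` short-read mapping. `N`
never matches on either side. Among placements tied at the minimal mismatch
count, one is chosen uniformly at random by a generator keyed on
`(read_id, seed)` (default seed 1715, recorded in output headers), so
results are reproducible yet independent of batch composition and order.
Random tie assignment is essential: deterministic first-reference
assignment would pile every read of a multi-copy gene onto one copy,
whereas uniform assignment splits them near-evenly — which is what
best-hit mappers do in practice and what makes isodecoder-level sums exact.
The implementation is a full scan with early termination, certified in the
test suite against an independent brute-force Hamming oracle (identical
best mismatch counts, reported placement within the oracle's best
stratum).

## Two-round classification and counting

Round 1 maps preprocessed reads to the artificial genome and classifies
each read by its best placement:

* masked chromosome → **non-tRNA**;
* decoy, fully inside the gene-body interval → **mature**;
* decoy, overlapping a flank by one base or more → **premature**;
* no placement within 3 mismatches → **unmapped**.

Containment is strict: "without the flanking sequences" is read as
excluding any flank-derived base, and the boundary behavior is pinned by a
sweep test. Round 2 takes the mature reads plus non-tRNA reads strictly
shorter than 30 nt (short reads may be mature fragments whose genomic copy
is masked) and maps them to the mature reference; unmapped round-1 reads
are not carried forward. Counting covers the cytosolic, high-confidence,
non-pseudogene set; the mature reference itself keeps all genes, so
excluded genes absorb their own reads (tallied in a drop report) instead of
contaminating neighbors. Individual counts aggregate by name truncation to
isodecoders (`tRNA-Ala-AGC-2`) and isoacceptors (`tRNA-Ala-AGC`); column
totals are conserved exactly, and merging the two printed copy counts
551 and 560 into 1111 is kept as a permanent test.

## Filtering and differential expression

Counts per million use raw or TMM-effective library sizes; the prevalence
filter keeps an entity when its CPM is at least `min_cpm = 1` in at least
`ceiling(0.9 × n)` samples. The DE path is implemented natively and follows
the edgeR lineage:

* **TMM normalization** — reference sample with upper-quartile CPM closest
  to the mean; M and A values over genes expressed in both samples; 30%
  two-sided trim on M and 5% on A; factor `2^` the
  inverse-asymptotic-variance weighted mean of M; factors rescaled to
  geometric mean 1. Cross-checked against an independent implementation in
  the test suite.
* **Common dispersion** — counts are equalized to the geometric-mean
  effective library size (pseudo-counts, rounded half-to-even, so the
  conditional argument below applies), and a single NB dispersion `phi`
  maximizes the conditional log-likelihood given each group's gene-wise
  total, searched numerically on `[1e-6, 4]`. Parameter-recovery
  simulations (Poisson truth and `phi = 0.4` truth) bound the estimator in
  the tests.
* **Exact test** — conditional on the total `t = sum_A + sum_B`, group sums
  are NB with sizes `n_A/phi`, `n_B/phi`; the two-sided p-value sums the
  conditional probabilities of all outcomes no more likely than the
  observed one. As `phi → 0` this reduces to the exact binomial doubling
  test, which serves as the closed-form oracle in the tests. Type-I error
  is checked by a null simulation (500 genes, 5 vs 5, `phi = 0.2`).
* **Multiple testing** — Bonferroni and Benjamini–Hochberg columns are both
  emitted; BH is the FDR column (the two names denote the same step-up
  procedure here). The significance flag is
  `|log2FC| > log2(1.5)` and adjusted `p < 0.05` by default.

Fold changes are smoothed with a prior count of 0.125 per sample on the CPM
scale so that all-zero groups stay finite; `avgLog2CPM` is the mean of
`log2(CPM + prior)`. There is no F-statistic column: the exact-test path
has none, and the quasi-likelihood and limma/DESeq2-style alternatives are
out of scope by design.

## Visualization data

Plot data frames are first-class outputs; rendering is a thin ggplot2
layer. Sample distances for MDS follow the leading log-fold-change
convention — root-mean-square of the `top_k = 500` largest absolute
log2-CPM differences per sample pair — followed by classical Torgerson
scaling with a deterministic sign convention (first nonzero loading
positive). Volcano status is `up`/`down`/`ns` from the significance flag
and sign; the anticodon bar counts significant isodecoders per
isotype–anticodon family; the amino-acid pyramid counts significant
isoacceptors per isotype.

## The synthetic-data generator

`simulate_genome()` plants tRNA genes in random background: two 10 kb
chromosomes and 12 genes by default, gene spans of 70–90 nt, a 20% chance
of a 10–20 nt intron, half the genes on the minus strand, 10% pseudogenes,
and a 20% chance that a gene is an exact sequence copy of an earlier one
(exercising isodecoder grouping, as multi-copy tRNA loci are the norm in
real genomes). Planted genes are kept more than 60 nt apart so no decoy
flank swallows a neighboring gene body. The annotation is emitted in the
exact tRNAscan-SE dialect the parser consumes, and parsing it recovers the
planted coordinates bit-exactly.

`simulate_reads()` draws read origins from a 70/15/15
mature/premature/background mixture: mature fragments from the mature
sequences (half 3'-anchored over the CCA by default, `frac_3p = 0.5`, and
gene choice proportional to log-normal abundances), premature fragments
straddling a decoy flank/gene junction, and background fragments at least
1 kb from any gene. Substitution errors (0.5% per base), optional adapter
read-through with truncation at the machine read length, and a Gaussian
Phred profile complete the model. Everything is deterministic given the
seed, and per-read origin labels plus per-gene true counts are recorded.

The generator emulates read *origin structure*, not sequencing chemistry:
no reverse-transcription stops at modified bases, no tRF biogenesis, no
ligation bias, no quality-dependent errors. Passing recovery tests
therefore demonstrates that the classification and counting machinery is
correct under the stated mixture — not that real libraries are free of
those biologically induced biases.

## Validation experiment design

Two properties of the two-round rule shape what "recovery" can mean, and
both follow analytically from the classification contract:

* **CCA-straddle loss.** A mature read that covers any CCA base cannot sit
  fully inside a decoy's gene body: its best round-1 placement straddles
  the gene/flank junction and is classified premature, so it never reaches
  round 2. With `frac_3p = 0.5` roughly half of all mature reads are lost
  this way — proportionally across genes, so ranks survive.
* **Splice-junction loss.** A mature read spanning an intron's splice
  junction has no contiguous placement on the unspliced decoy and is
  typically unmapped in round 1, so intron-bearing genes are
  systematically undercounted relative to intron-free ones.
* **Copy ambiguity.** For sequence-identical loci the read-to-copy
  assignment is a uniform tie-break; per-copy truth is unrecoverable by
  any best-hit method, while isodecoder sums are exact.

Exact-recovery experiments therefore run in the identifiable regime
(`interior_only = TRUE`, `intron_prob = 0`, `dup_fraction = 0`,
`error_rate = 0`), where estimated individual counts must equal the truth
read for read. The mixed-origin rank-recovery experiment (50,000 reads, 30
genes, 0.5% error, default origin mixture) keeps the default 3'-anchoring
but uses unique, intron-free gene bodies; the duplicate-copy regime is
asserted separately (binomial split bounds at the individual level,
exact conservation and rank recovery at the isodecoder level). Problem
sizes throughout the suite (toy genomes of 6–20 kb, hundreds to tens of
thousands of reads, 500-gene DE simulations) were chosen as the smallest
sizes at which the statistical assertions have useful power.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; the tRNAscan-SE dialect
  (1-based inclusive, begin > end on the minus strand) is converted at the
  parse boundary and intron coordinates are re-expressed gene-locally after
  orientation.
* Tie-breaking uses a splitmix64 stream keyed by FNV-1a(read id) XOR the
  seed; reservoir sampling gives exact uniformity over the best stratum in
  one pass.
* Pseudo-count equalization rounds half-to-even (R's `round()`), making the
  DE path fully deterministic.
* `optimize()` on `[1e-6, 4]` for the dispersion; two identical columns
  drive the estimate to the lower bound, and an all-zero matrix is
  rejected.
* Empty inputs degrade gracefully: empty annotations give empty bundles,
  empty FASTQs give all-zero QC reports and tallies, empty DE tables give
  empty plot data.
* A sample with no genes usable for TMM gets factor 1 with a warning;
  a zero library size is an error.

## Limitations

tRNA-derived fragments are not identified or separated; short tRFs that
fall inside a gene body are counted as mature signal, a known confounder of
small RNA-seq tRNA quantification. CCA-straddling and splice-junction reads
are systematically lost, as described above, so absolute abundances are
thinned; comparisons between conditions are unaffected because the
thinning is gene-wise constant. The DE module supports exactly two groups
with no batch covariates, and only the common-dispersion exact test.
Modification-induced misincorporation, CCA-vs-CC discrimination and gapped
alignment are out of scope.
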
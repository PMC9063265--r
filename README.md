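# trnaquant

Quantification of **mature transfer RNA expression from single-end small
RNA-seq**, with two-group differential expression and plot-ready result
tables. The package is aimed at researchers who have small RNA-seq FASTQ
files, a genome, and a tRNAscan-SE annotation, and want per-tRNA count
matrices and differentially expressed tRNAs (DEtRNAs) without stitching
together a genome-masking, alignment and statistics pipeline by hand.

## The method

Reads from a small RNA library are a mixture of mature tRNAs, premature
transcripts and unrelated genomic background, and tRNA genes occur in
near-identical multi-copy families. `trnaquant` separates these signals
with a purpose-built reference and a two-round best-hit mapping:

1. **Artificial genome** — every annotated tRNA gene span is masked to `N`,
   and each gene is re-appended as a *premature decoy chromosome*: the
   unspliced gene body plus up to 50 nt of flanking sequence per side.
   A separate **mature reference** carries each gene spliced, strand
   oriented, with the post-transcriptional 3′ `CCA` appended.
2. **Round 1** aligns reads to the artificial genome (end-to-end, ungapped,
   ≤ 3 mismatches, best hit, ties broken uniformly at random with a
   recorded seed) and classifies them by placement: masked chromosome →
   *non-tRNA*; decoy fully inside the gene body → *mature*; any flank
   overlap → *premature*.
3. **Round 2** re-aligns the mature reads (plus non-tRNA reads < 30 nt) to
   the mature reference and counts them over the cytosolic,
   high-confidence, non-pseudogene set, at three levels: individual tRNA
   (`tRNA-Ala-AGC-2-1`), isodecoder (`tRNA-Ala-AGC-2` — same body
   sequence), and isoacceptor (`tRNA-Ala-AGC` — same anticodon), by exact
   count merging.
4. **Statistics** — CPM prevalence filtering (CPM ≥ 1 in ≥ 90% of
   samples), TMM normalization, a common-dispersion negative-binomial
   exact test on library-size-equalized pseudo-counts
   (p = Σ P(outcomes no more likely than observed | group total)),
   Bonferroni and Benjamini–Hochberg adjustment, and significance at
   |log2FC| > log2(1.5), adjusted p < 0.05.
5. **Plots** — MDS on leading-logFC sample distances, volcano, per-anticodon
   bar and per-amino-acid pyramid data tables, each with a thin ggplot2
   renderer.

A synthetic-data module (`sim_config()`, `simulate_genome()`,
`simulate_reads()`) generates toy genomes with planted tRNA genes and read
sets with known per-read origins and per-gene true counts, so every stage
is testable with no downloads. See `vignette("trnaquant-methods")` for the
full model, parameter rationale and known limitations.

## Worked example

Simulate a study, preprocess, and quantify one sample:

```r
library(trnaquant)

cfg <- sim_config(seed = 7, n_reads = 4000, n_genes = 10, error_rate = 0.005,
                  adapter = "TGGAATTCTCGGTGGTCGCCGTATCATT")
sim    <- simulate_genome(cfg)
genes  <- assign_gtrnadb_names(parse_trna_annotation(sim$annotation,
                                                     sim$genome), sim$genome)
bundle <- build_bundle(sim$genome, genes)
bundle
#> genome_bundle: 2 masked chromosome(s), 10 premature decoy record(s), 10 mature record(s)

rd <- simulate_reads(bundle, cfg, fastq = "reads.fastq")
pp <- preprocess_fastq("reads.fastq", "clean.fastq",
                       preprocess_params(min_quality = 25, min_len = 15))
pp$report
#> qc_report: total=4000 adapter_matched=4000 too_short=0 low_quality=0 passed=4000

q <- quantify_sample("clean.fastq", bundle)
q$tally
#>      n_input   n_unmapped   n_non_trna  n_premature  n_mature_r1   n_selected
#>         4000          416          575         1829         1180         1422
#> n_counted_r2
#>         1180
head(sort(q$counts, decreasing = TRUE), 5)
#> tRNA-Gln-CTG-1-1 tRNA-Pro-AGG-1-3 tRNA-Pro-AGG-1-2 tRNA-Pro-AGG-1-1
#>              209              188              171              163
#> tRNA-Cys-GCA-1-1
#>              136
```

Every read gets exactly one first-round class (the four tallies sum to
`n_input`). The three `tRNA-Pro-AGG-1-*` loci are exact sequence copies:
best-hit ties are split uniformly at random among them, so their individual
counts are nearly equal while their isodecoder sum is exact:

```r
iso <- aggregate_counts(q$counts, "isodecoder")
head(iso[order(-iso[, 1]), , drop = FALSE], 3)
#>                sample1
#> tRNA-Pro-AGG-1     522
#> tRNA-Gln-CTG-1     209
#> tRNA-Cys-GCA-1     136
```

With a sample sheet (`sample`, `fastq`, `group`) the whole workflow —
genome build, QC, quantification at all three levels, filtering, DE and
plot data — runs as one call, `run_pipeline(pipeline_config(...))`, or from
a shell via the launcher `inst/cli/trnaquant.R`
(`build-genome`, `preprocess`, `quantify`, `filter`, `de`, `plot`,
`simulate`, `run-all`; see `trnaquant_cli("help")`). All outputs are
tab-delimited text with provenance headers recording parameters and seed.

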
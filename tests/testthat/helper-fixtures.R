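# Shared fixtures built in code: a tiny hand-laid genome with known tRNA
# genes, and the 10-read QC FASTQ whose report partition is forced by
# construction.

# Deterministic toy genome: two chromosomes, two genes with identical mature
# sequence (one per strand), one intron-bearing gene, one pseudogene.
make_toy_genome <- function() {
  set.seed(901)
  chr1 <- random_dna(6000)
  chr2 <- random_dna(6000)
  gene_a <- random_dna(72)                       # planted at chr1:2400 (+)
  gene_b <- random_dna(80)                       # chr1:2900 (+), intron 30-45
  gene_c <- gene_a                               # chr2:2500 (-), same sequence
  gene_d <- random_dna(75)                       # chr2:3200 (+), pseudogene
  substr(chr1, 2401, 2472) <- gene_a
  substr(chr1, 2901, 2980) <- gene_b
  substr(chr2, 2501, 2572) <- oracle_revcomp(gene_c)
  substr(chr2, 3201, 3275) <- gene_d
  genome <- c(chr1 = chr1, chr2 = chr2)
  annotation <- c(
    "chr1\t1\t2401\t2472\tAla\tAGC\t0\t0\t80.0\thigh confidence set",
    "chr1\t2\t2901\t2980\tGly\tGCC\t2931\t2945\t75.5\thigh confidence set",
    "chr2\t1\t2572\t2501\tAla\tAGC\t0\t0\t79.0\thigh confidence set",
    "chr2\t2\t3201\t3275\tSer\tAGA\t0\t0\t30.1\tpseudo")
  list(genome = genome, annotation = annotation,
       gene_seqs = list(a = gene_a, b = gene_b, c = gene_c, d = gene_d))
}

make_toy_bundle <- function(flank_len = 50L) {
  toy <- make_toy_genome()
  genes <- parse_trna_annotation(toy$annotation, toy$genome)
  genes <- assign_gtrnadb_names(genes, toy$genome)
  build_bundle(toy$genome, genes, flank_len)
}

# Ten-read QC fixture: 4 adapter-bearing reads with >= 15 nt high-quality
# inserts, 3 whose inserts trim below 15 nt, 3 adapter-free low-quality
# reads. Returns the FASTQ path.
make_qc_fixture <- function(path) {
  adapter <- "TGGAATTCTCGGTGGTCGCCGTATCATT"
  q <- function(len, phred) paste(rep(rawToChar(as.raw(phred + 33L)), len),
                                  collapse = "")
  set.seed(77)
  inserts_ok <- replicate(4, random_dna(20))
  ids <- character(0); seqs <- character(0); quals <- character(0)
  for (i in 1:4) {
    s <- paste0(inserts_ok[i], adapter)
    ids <- c(ids, sprintf("pass%d", i)); seqs <- c(seqs, s)
    quals <- c(quals, q(nchar(s), 37))
  }
  for (i in 1:3) {
    s <- paste0(random_dna(5), adapter)
    ids <- c(ids, sprintf("short%d", i)); seqs <- c(seqs, s)
    quals <- c(quals, q(nchar(s), 37))
  }
  for (i in 1:3) {
    # ends in AAAA: cannot match the TGG... adapter prefix at any overlap
    s <- paste0(random_dna(16), "AAAA")
    ids <- c(ids, sprintf("lowq%d", i)); seqs <- c(seqs, s)
    quals <- c(quals, q(nchar(s), 12))
  }
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}

spearman <- function(x, y) stats::cor(x, y, method = "spearman")
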
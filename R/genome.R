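# Artificial and mature tRNA genome construction.
#
# The artificial genome is the input genome with every annotated tRNA gene
# span masked to N, plus one "premature" decoy chromosome per gene (gene body
# with up to 50 nt of flanking sequence on either side, oriented to the gene
# strand, introns retained). The mature reference holds one record per gene:
# spliced, strand-oriented, with the post-transcriptional 3' CCA appended.

PREMATURE_PREFIX <- "preTRNA::"

#' Extract the mature (spliced, CCA-tailed) sequence of a tRNA gene
#'
#' @param gene one-row data.frame (a row of the gene table).
#' @param genome named character vector of chromosome sequences.
#' @return upper-case DNA string ending in `"CCA"`.
#' @export
extract_mature_sequence <- function(gene, genome) {
  span <- toupper(substr(genome[[gene$chrom]], gene$start + 1, gene$end))
  if (gene$strand == "-") span <- revcomp(span)
  is_ <- gene$intron_starts[[1L]]
  ie_ <- gene$intron_ends[[1L]]
  if (length(is_)) {
    if (any(is_ < 0) || any(ie_ > nchar(span)) || any(is_ >= ie_)) {
      stop("intron outside gene span for gene at ", gene$chrom, ":", gene$start)
    }
    for (j in rev(seq_along(is_))) {
      span <- paste0(substr(span, 1, is_[j]), substr(span, ie_[j] + 1, nchar(span)))
    }
  }
  paste0(span, "CCA")
}

#' Build the premature tRNA decoy library
#'
#' One record per gene: up to `flank_len` nt of upstream flank (truncated at
#' the chromosome edge), the unspliced gene body, and up to `flank_len` nt of
#' downstream flank, oriented to the gene strand. The stored
#' `upstream_flank_len` and `gene_len` make the pure-tRNA interval
#' recoverable for read classification.
#'
#' @param genes named gene table.
#' @param genome named character vector of chromosome sequences.
#' @param flank_len flank length in nt (default 50).
#' @return data.frame with columns `ref_name`, `gene_name`, `seq`,
#'   `upstream_flank_len`, `gene_len`.
#' @export
build_premature_library <- function(genes, genome, flank_len = 50L) {
  stopifnot(flank_len >= 0)
  if (!nrow(genes)) {
    return(data.frame(ref_name = character(0), gene_name = character(0),
                      seq = character(0), upstream_flank_len = integer(0),
                      gene_len = integer(0), stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    L <- nchar(genome[[g$chrom]])
    f_left <- min(flank_len, g$start)
    f_right <- min(flank_len, L - g$end)
    win <- toupper(substr(genome[[g$chrom]], g$start - f_left + 1, g$end + f_right))
    if (g$strand == "-") {
      win <- revcomp(win)
      upstream <- f_right
    } else {
      upstream <- f_left
    }
    list(ref_name = paste0(PREMATURE_PREFIX, g$name), gene_name = g$name,
         seq = win, upstream_flank_len = as.integer(upstream),
         gene_len = as.integer(g$end - g$start))
  })
  data.frame(ref_name = vapply(recs, `[[`, "", "ref_name"),
             gene_name = vapply(recs, `[[`, "", "gene_name"),
             seq = vapply(recs, `[[`, "", "seq"),
             upstream_flank_len = vapply(recs, `[[`, 0L, "upstream_flank_len"),
             gene_len = vapply(recs, `[[`, 0L, "gene_len"),
             stringsAsFactors = FALSE)
}

#' Mask annotated tRNA gene spans with N
#'
#' Every annotated gene span is replaced by a run of `N` of equal length;
#' all other positions, and all chromosome lengths, are unchanged.
#' Overlapping annotations mask idempotently.
#'
#' @inheritParams build_premature_library
#' @return named character vector, same names and lengths as `genome`.
#' @export
mask_genome <- function(genome, genes) {
  out <- genome
  if (nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      substr(out[[g$chrom]], g$start + 1, g$end) <-
        strrep("N", g$end - g$start)
    }
  }
  out
}

#' Build the full genome bundle (artificial + mature genomes + registry)
#'
#' @inheritParams build_premature_library
#' @return an object of class `genome_bundle`: list with `masked` (named
#'   character vector), `premature` (decoy record table), `mature` (named
#'   character vector of CCA-tailed sequences, named by gene), `registry`
#'   (one row per reference sequence with its role and owning gene) and
#'   `genes`. Filtering to cytosolic/high-confidence genes happens at
#'   counting time, not here.
#' @export
build_bundle <- function(genome, genes, flank_len = 50L) {
  if (nrow(genes) && anyNA(genes$name)) {
    stop("genes must be named first (see assign_gtrnadb_names)")
  }
  masked <- mask_genome(genome, genes)
  prem <- build_premature_library(genes, genome, flank_len)
  if (any(prem$ref_name %in% names(genome))) {
    stop("premature record name collides with a genomic chromosome name")
  }
  mature <- if (nrow(genes)) {
    stats::setNames(vapply(seq_len(nrow(genes)), function(i) {
      extract_mature_sequence(genes[i, ], genome)
    }, ""), genes$name)
  } else {
    stats::setNames(character(0), character(0))
  }
  registry <- data.frame(
    ref_name = names(genome), role = "genomic",
    gene_name = NA_character_, upstream_flank_len = NA_integer_,
    gene_len = NA_integer_, isotype = NA_character_,
    anticodon = NA_character_, high_confidence = NA,
    cytosolic = NA, pseudo = NA, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    registry <- rbind(
      registry,
      data.frame(ref_name = prem$ref_name, role = "premature",
                 gene_name = prem$gene_name,
                 upstream_flank_len = prem$upstream_flank_len,
                 gene_len = prem$gene_len, isotype = genes$isotype,
                 anticodon = genes$anticodon,
                 high_confidence = genes$high_confidence,
                 cytosolic = genes$cytosolic, pseudo = genes$pseudo,
                 stringsAsFactors = FALSE),
      data.frame(ref_name = names(mature), role = "mature",
                 gene_name = names(mature), upstream_flank_len = NA_integer_,
                 gene_len = NA_integer_, isotype = genes$isotype,
                 anticodon = genes$anticodon,
                 high_confidence = genes$high_confidence,
                 cytosolic = genes$cytosolic, pseudo = genes$pseudo,
                 stringsAsFactors = FALSE))
  }
  structure(list(masked = masked, premature = prem, mature = mature,
                 registry = registry, genes = genes, flank_len = flank_len),
            class = "genome_bundle")
}

#' Artificial genome of a bundle
#'
#' Masked chromosomes plus the premature decoy records, as one named
#' character vector (first-round mapping reference).
#' @param bundle a `genome_bundle`.
#' @return named character vector.
#' @export
artificial_genome <- function(bundle) {
  c(bundle$masked, stats::setNames(bundle$premature$seq, bundle$premature$ref_name))
}

#' Write bundle artifacts to disk
#'
#' Writes `artificial_genome.fa`, `mature_genome.fa` (60-column FASTA),
#' `registry.tsv` and `genes.tsv` under `dir`.
#' @param bundle a `genome_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(artificial_genome(bundle), file.path(dir, "artificial_genome.fa"))
  write_fasta(bundle$mature, file.path(dir, "mature_genome.fa"))
  write_tsv(bundle$registry, file.path(dir, "registry.tsv"),
            header = provenance_header(list(flank_len = bundle$flank_len)))
  g <- bundle$genes
  g$intron_starts <- vapply(g$intron_starts, paste, "", collapse = ",")
  g$intron_ends <- vapply(g$intron_ends, paste, "", collapse = ",")
  write_tsv(g, file.path(dir, "genes.tsv"),
            header = provenance_header(list(flank_len = bundle$flank_len)))
  invisible(dir)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$masked), "masked chromosome(s),",
      nrow(x$premature), "premature decoy record(s),",
      length(x$mature), "mature record(s)\n")
  invisible(x)
}
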
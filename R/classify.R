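# Two-round read classification and mature tRNA counting.
#
# Round 1 (vs the artificial genome) assigns each read one class:
#   unmapped  - no placement within k mismatches
#   non_trna  - best hit on a masked genomic chromosome
#   mature    - best hit fully inside the gene body of a premature decoy
#   premature - best hit on a decoy overlapping a flank by >= 1 base
# Round 2 (vs the mature reference) counts the selected reads over the
# cytosolic, high-confidence, non-pseudogene set at three aggregation levels.

READ_CLASSES <- c("unmapped", "non_trna", "premature", "mature")

#' Classify first-round alignment hits
#'
#' @param hits data.frame from [align_batch()] against the artificial genome
#'   (rows with `NA` `ref_name` are unmapped reads).
#' @param registry the registry of a `genome_bundle`.
#' @return character vector of classes, parallel to `hits`.
#' @export
classify_first_round <- function(hits, registry) {
  if (!nrow(hits)) return(character(0))
  m <- match(hits$ref_name, registry$ref_name)
  unknown <- !is.na(hits$ref_name) & is.na(m)
  if (any(unknown)) {
    stop("hit on unknown reference: ", hits$ref_name[which(unknown)[1L]])
  }
  cls <- rep("unmapped", nrow(hits))
  role <- registry$role[m]
  cls[!is.na(role) & role == "genomic"] <- "non_trna"
  prem <- which(!is.na(role) & role == "premature")
  if (length(prem)) {
    uf <- registry$upstream_flank_len[m[prem]]
    gl <- registry$gene_len[m[prem]]
    p <- hits$pos[prem]
    contained <- p >= uf & (p + hits$read_len[prem]) <= (uf + gl)
    cls[prem] <- ifelse(contained, "mature", "premature")
  }
  cls
}

#' Select reads for the second mapping round
#'
#' Mature-classified reads of any length, plus non-tRNA reads strictly
#' shorter than `len_threshold` nt; premature and unmapped reads are
#' excluded.
#'
#' @param classes character vector of first-round classes.
#' @param read_len integer read lengths, parallel to `classes`.
#' @param len_threshold strict upper bound for the non-tRNA carry-forward
#'   (default 30).
#' @return logical selection vector.
#' @export
select_second_round <- function(classes, read_len, len_threshold = 30L) {
  stopifnot(length(classes) == length(read_len))
  classes == "mature" | (classes == "non_trna" & read_len < len_threshold)
}

#' Count second-round hits per individual tRNA
#'
#' Only genes that are cytosolic, high-confidence and not pseudogenes are
#' counted; reads whose best hit lands on an excluded gene are dropped and
#' tallied in the drop report.
#'
#' @param hits data.frame from [align_batch()] against the mature reference.
#' @param registry the registry of a `genome_bundle`.
#' @return list with `counts` (named integer vector over every included
#'   gene, zeros kept) and `drop_report` (data.frame gene/reads for excluded
#'   genes that absorbed reads).
#' @export
count_individual <- function(hits, registry) {
  mat <- registry[registry$role == "mature", , drop = FALSE]
  included <- mat$cytosolic & mat$high_confidence & !mat$pseudo
  counts <- stats::setNames(integer(sum(included)), mat$gene_name[included])
  mapped <- hits[!is.na(hits$ref_name), , drop = FALSE]
  if (nrow(mapped)) {
    unknown <- !(mapped$ref_name %in% mat$ref_name)
    if (any(unknown)) {
      stop("second-round hit on unknown mature reference: ",
           mapped$ref_name[which(unknown)[1L]])
    }
    tab <- table(mapped$ref_name)
    gene <- mat$gene_name[match(names(tab), mat$ref_name)]
    keep <- gene %in% names(counts)
    counts[gene[keep]] <- counts[gene[keep]] + as.integer(tab[keep])
    drop <- data.frame(gene = gene[!keep],
                       reads = as.integer(tab[!keep]),
                       stringsAsFactors = FALSE)
  } else {
    drop <- data.frame(gene = character(0), reads = integer(0),
                       stringsAsFactors = FALSE)
  }
  list(counts = counts, drop_report = drop)
}

#' Aggregate a count table across tRNA naming levels
#'
#' Individual names (`tRNA-Ala-AGC-2-1`) collapse to isodecoders by dropping
#' the copy field (`tRNA-Ala-AGC-2`) and to isoacceptors by also dropping the
#' group field (`tRNA-Ala-AGC`); counts are summed per key and rows are
#' ordered lexicographically. Column sums are conserved.
#'
#' @param counts integer matrix (entities x samples) or named vector; row
#'   names at the individual or isodecoder level.
#' @param level target level: `"isodecoder"` or `"isoacceptor"` (or
#'   `"individual"`, a no-op).
#' @return integer matrix at the requested level.
#' @export
aggregate_counts <- function(counts, level = c("isodecoder", "isoacceptor",
                                               "individual")) {
  level <- match.arg(level)
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), "sample1"))
  }
  from <- name_level(rownames(counts))
  steps <- c(individual = 3L, isodecoder = 2L, isoacceptor = 1L)
  if (steps[[from]] < steps[[level]]) {
    stop("cannot disaggregate from ", from, " to ", level)
  }
  keys <- rownames(counts)
  for (s in seq_len(steps[[from]] - steps[[level]])) {
    keys <- strip_name_field(keys)
  }
  out <- rowsum(counts, group = keys, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

# Detect the naming level of a set of row names (validates parseability).
name_level <- function(x) {
  for (lv in c("individual", "isodecoder", "isoacceptor")) {
    ok <- tryCatch({ parse_trna_name(x, lv); TRUE }, error = function(e) FALSE)
    if (ok) return(lv)
  }
  stop("row names are not parseable tRNA names at any level")
}

#' Quantify one sample end to end
#'
#' Runs first-round mapping against the artificial genome, classification,
#' second-round selection, mapping against the mature reference, and
#' counting.
#'
#' @param reads preprocessed reads: named character vector,
#'   `Biostrings::DNAStringSet`, or a FASTQ path.
#' @param bundle a `genome_bundle`.
#' @param k maximum mismatches per round (default 3).
#' @param seed tie-break seed (default 1715).
#' @param len_threshold strict length bound for the non-tRNA carry-forward.
#' @return list with `counts` (individual-level named integer vector),
#'   `tally` (named integer vector: `n_input`, `n_unmapped`, `n_non_trna`,
#'   `n_premature`, `n_mature_r1`, `n_selected`, `n_counted_r2`),
#'   `classes` (per-read data.frame) and `drop_report`.
#' @export
quantify_sample <- function(reads, bundle, k = 3L, seed = 1715L,
                            len_threshold = 30L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    fq <- read_fastq(reads)
    reads <- stats::setNames(fq$seq, fq$id)
  }
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  empty_tally <- c(n_input = 0L, n_unmapped = 0L, n_non_trna = 0L,
                   n_premature = 0L, n_mature_r1 = 0L, n_selected = 0L,
                   n_counted_r2 = 0L)
  counts0 <- count_individual(
    data.frame(read_id = character(0), ref_name = character(0),
               pos = integer(0), strand = character(0),
               mismatches = integer(0), read_len = integer(0)),
    bundle$registry)
  if (!length(reads)) {
    return(list(counts = counts0$counts, tally = empty_tally,
                classes = data.frame(read_id = character(0),
                                     class = character(0),
                                     read_len = integer(0)),
                drop_report = counts0$drop_report))
  }
  idx1 <- build_index(artificial_genome(bundle))
  hits1 <- align_batch(idx1, reads, k = k, seed = seed)
  cls <- classify_first_round(hits1, bundle$registry)
  sel <- select_second_round(cls, hits1$read_len, len_threshold)
  tally <- c(n_input = length(reads),
             n_unmapped = sum(cls == "unmapped"),
             n_non_trna = sum(cls == "non_trna"),
             n_premature = sum(cls == "premature"),
             n_mature_r1 = sum(cls == "mature"),
             n_selected = sum(sel), n_counted_r2 = 0L)
  if (any(sel) && length(bundle$mature)) {
    idx2 <- build_index(
      stats::setNames(bundle$mature, names(bundle$mature)))
    hits2 <- align_batch(idx2, reads[hits1$read_id[sel]], k = k, seed = seed)
    res <- count_individual(hits2, bundle$registry)
  } else {
    res <- counts0
  }
  tally["n_counted_r2"] <- sum(res$counts)
  list(counts = res$counts, tally = tally,
       classes = data.frame(read_id = hits1$read_id, class = cls,
                            read_len = hits1$read_len,
                            stringsAsFactors = FALSE),
       drop_report = res$drop_report)
}

#' Quantify several samples into a count matrix
#'
#' @param fastqs named character vector of FASTQ paths (or a named list of
#'   read vectors); names become sample names.
#' @inheritParams quantify_sample
#' @return list with `counts` (individual-level integer matrix genes x
#'   samples) and `tallies` (samples x classes matrix).
#' @export
quantify_samples <- function(fastqs, bundle, k = 3L, seed = 1715L,
                             len_threshold = 30L) {
  stopifnot(length(fastqs) > 0, !is.null(names(fastqs)))
  res <- lapply(fastqs, quantify_sample, bundle = bundle, k = k, seed = seed,
                len_threshold = len_threshold)
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- names(fastqs)
  tallies <- do.call(rbind, lapply(res, `[[`, "tally"))
  rownames(tallies) <- names(fastqs)
  list(counts = counts, tallies = tallies)
}
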
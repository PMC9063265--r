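# Native ungapped best-hit short-read aligner.
#
# Contract: every end-to-end ungapped placement of the read on both strands
# of every reference is considered; a placement with the minimum Hamming
# distance (<= k) is returned, ties broken uniformly at random with an RNG
# keyed by (read_id, seed) so that per-read results are independent of batch
# composition and order. N never matches, on either side.

#' Build an alignment index over a reference set
#'
#' @param references named character vector of DNA sequences over
#'   `{A,C,G,T,N}`.
#' @return an object of class `ref_index`.
#' @export
build_index <- function(references) {
  if (!length(references)) stop("empty reference set")
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("references must be named")
  }
  if (anyDuplicated(names(references))) stop("duplicate reference names")
  structure(list(names = names(references),
                 seqs = toupper(unname(as.character(references)))),
            class = "ref_index")
}

#' Align one read (best hit, up to k mismatches)
#'
#' @param index a `ref_index`.
#' @param read DNA string (length must exceed `k`).
#' @param k maximum mismatches (default 3, the `-v 3` contract).
#' @param seed integer seed keying the tie-break RNG (default 1715).
#' @param read_id identifier keying the per-read RNG stream.
#' @return one-row data.frame (`read_id`, `ref_name`, `pos`, `strand`,
#'   `mismatches`, `read_len`) or `NULL` when no placement has <= k
#'   mismatches. `pos` is the 0-based offset of the read's leftmost base on
#'   the + strand of the reference.
#' @export
align_read <- function(index, read, k = 3L, seed = 1715L, read_id = "read1") {
  hits <- align_batch(index, stats::setNames(read, read_id), k = k, seed = seed)
  if (is.na(hits$ref_name[1L])) NULL else hits[1L, , drop = FALSE]
}

#' Align a batch of reads
#'
#' Deterministic given (reads, seed); the tie-break RNG is keyed per
#' `read_id`, so per-read results are invariant under permutation of the
#' batch.
#'
#' @param index a `ref_index`.
#' @param reads named character vector (names are read ids) or
#'   `Biostrings::DNAStringSet`.
#' @param k maximum mismatches.
#' @param seed integer tie-break seed.
#' @return data.frame with one row per read: `read_id`, `ref_name`, `pos`,
#'   `strand`, `mismatches`, `read_len`; alignment columns are `NA` for
#'   unmapped reads.
#' @export
align_batch <- function(index, reads, k = 3L, seed = 1715L) {
  stopifnot(inherits(index, "ref_index"))
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  ids <- names(reads)
  if (length(reads) && (is.null(ids) || any(!nzchar(ids)))) {
    stop("reads must be named by read_id")
  }
  if (anyDuplicated(ids)) stop("duplicate read_id in batch")
  if (!length(reads)) {
    return(data.frame(read_id = character(0), ref_name = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), read_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (any(nchar(reads) < k + 1L)) {
    stop("read shorter than k + 1 (", k + 1L, " nt)")
  }
  res <- .align_batch_cpp(index$seqs, ids, toupper(unname(reads)),
                          as.integer(k), as.numeric(seed))
  data.frame(read_id = ids,
             ref_name = index$names[res$ref],
             pos = res$pos,
             strand = c("+", "-")[res$strand + 1L],
             mismatches = res$mismatches,
             read_len = res$read_len,
             stringsAsFactors = FALSE)
}

#' Write a hit table as TSV
#' @param hits data.frame from [align_batch()].
#' @param path output path.
#' @param params named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, params = list()) {
  write_tsv(hits, path, header = provenance_header(params))
}

#' Minimal SAM emission for a hit table
#'
#' Unsorted records with FLAG 0/16/4, 1-based POS, full-length match CIGAR
#' and an NM tag; a minimal `@SQ` header is derived from the index.
#'
#' @param hits data.frame from [align_batch()].
#' @param index the `ref_index` the hits were produced against.
#' @param reads the named read vector (sequences are echoed into SEQ).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
hits_to_sam <- function(hits, index, reads, path) {
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", index$names, nchar(index$seqs)))
  recs <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    seq <- toupper(reads[[h$read_id]])
    if (is.na(h$ref_name)) {
      return(paste(h$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, "*",
                   sep = "\t"))
    }
    flag <- if (h$strand == "-") 16L else 0L
    if (h$strand == "-") seq <- revcomp(seq)
    paste(h$read_id, flag, h$ref_name, h$pos + 1L, 255L,
          paste0(h$read_len, "M"), "*", 0L, 0L, seq, "*",
          paste0("NM:i:", h$mismatches), sep = "\t")
  }, "")
  writeLines(c(hdr, recs), path)
  invisible(path)
}
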
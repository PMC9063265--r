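# FASTQ preprocessing: 3' adapter trimming, minimum-length and mean-quality
# filtering, and the four-quantity QC report (total / adapter-matched /
# too-short / low-quality-vs-passed partition).

ADAPTER_PRESETS <- c(
  illumina_small_rna_3p = "TGGAATTCTCGGTGGTCGCCGTATCATT",
  illumina_universal = "AGATCGGAAGAGC",
  solid = "CGCCTTGGCCGT",
  none = ""
)

#' Preprocessing parameters
#'
#' @param adapter_preset one of `"illumina_small_rna_3p"`,
#'   `"illumina_universal"`, `"solid"`, `"none"`. The shipped sequences are
#'   conventional defaults and can be overridden with `adapter_seq`.
#' @param adapter_seq explicit adapter sequence (overrides the preset).
#' @param min_quality minimum mean Phred score; 25 and 30 are the
#'   conventional settings.
#' @param min_len minimum post-trim read length in nt (default 15).
#' @param min_overlap minimum adapter overlap for a trim (default 3).
#' @param max_mismatch_rate mismatch tolerance per overlap base (default 0.1).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter_preset = "illumina_small_rna_3p",
                              adapter_seq = NULL,
                              min_quality = 25, min_len = 15L,
                              min_overlap = 3L, max_mismatch_rate = 0.1) {
  adapter_preset <- match.arg(adapter_preset, names(ADAPTER_PRESETS))
  adapter <- if (!is.null(adapter_seq)) toupper(adapter_seq)
             else ADAPTER_PRESETS[[adapter_preset]]
  stopifnot(min_len >= 1, min_overlap >= 1, max_mismatch_rate >= 0)
  structure(list(adapter_preset = adapter_preset, adapter = adapter,
                 min_quality = min_quality, min_len = as.integer(min_len),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate),
            class = "preprocess_params")
}

#' Trim a 3' adapter from one read
#'
#' Finds the leftmost position `i` such that a prefix of the adapter matches
#' `substr(read, i+1, len)` end-anchored, with mismatches
#' `<= floor(max_mismatch_rate * overlap)` and overlap `>= min_overlap`; the
#' read (and its qualities) are truncated to the first `i` bases. Leftmost
#' match wins, i.e. the shortest insert, guarding against adapter
#' read-through.
#'
#' @param seq read sequence.
#' @param quals integer Phred scores (same length as `seq`), or `NULL`.
#' @param adapter adapter sequence.
#' @param min_overlap minimum overlap in nt.
#' @param max_mismatch_rate allowed mismatch fraction of the overlap.
#' @return list with `seq`, `quals`, and logical `matched`.
#' @export
trim_adapter <- function(seq, quals = NULL, adapter,
                         min_overlap = 3L, max_mismatch_rate = 0.1) {
  if (!nzchar(adapter)) return(list(seq = seq, quals = quals, matched = FALSE))
  ins <- .trim_adapter_batch_cpp(seq, toupper(adapter), as.integer(min_overlap),
                                 max_mismatch_rate)
  if (ins < 0) return(list(seq = seq, quals = quals, matched = FALSE))
  list(seq = substr(seq, 1L, ins),
       quals = if (is.null(quals)) NULL else quals[seq_len(ins)],
       matched = TRUE)
}

#' Mean-quality read filter
#'
#' A read passes when its mean Phred score is at least `min_quality`
#' (boundary inclusive); an empty read never passes.
#'
#' @param quals integer Phred scores.
#' @param min_quality threshold.
#' @return logical.
#' @export
passes_quality <- function(quals, min_quality) {
  length(quals) > 0 && mean(quals) >= min_quality
}

#' Preprocess a FASTQ file
#'
#' Per read: adapter trimming (unless the preset is `"none"`), then a length
#' gate (`too_short`), then the mean-quality gate (`low_quality`); surviving
#' reads are written out. The report partition
#' `passed + too_short + low_quality == total` holds exactly;
#' `adapter_matched` counts reads where a trim occurred.
#'
#' @param in_path input FASTQ (plain or gzip, Phred+33).
#' @param out_path output FASTQ for passed reads (gzip when the name ends in
#'   `.gz`).
#' @param params a [preprocess_params()] object.
#' @return list with `out_path` and `report` (class `qc_report`: `total`,
#'   `adapter_matched`, `too_short`, `low_quality`, `passed`).
#' @export
preprocess_fastq <- function(in_path, out_path, params = preprocess_params()) {
  fq <- read_fastq(in_path)
  n <- length(fq$seq)
  matched <- rep(FALSE, n)
  if (nzchar(params$adapter) && n > 0) {
    ins <- .trim_adapter_batch_cpp(fq$seq, params$adapter,
                                   params$min_overlap, params$max_mismatch_rate)
    matched <- ins >= 0
    trim_to <- ifelse(matched, ins, nchar(fq$seq))
    fq$seq <- substr(fq$seq, 1L, trim_to)
    fq$qual <- substr(fq$qual, 1L, trim_to)
  }
  len <- nchar(fq$seq)
  too_short <- len < params$min_len
  mean_q <- numeric(n)
  if (n > 0) {
    qlist <- as(Biostrings::PhredQuality(fq$qual), "IntegerList")
    mean_q <- vapply(qlist, function(q) if (length(q)) mean(q) else -Inf, 0)
  }
  low_quality <- !too_short & mean_q < params$min_quality
  passed <- !too_short & !low_quality
  write_fastq(fq$id[passed], fq$seq[passed], fq$qual[passed], out_path)
  report <- structure(list(total = n,
                           adapter_matched = sum(matched),
                           too_short = sum(too_short),
                           low_quality = sum(low_quality),
                           passed = sum(passed)),
                      class = "qc_report")
  list(out_path = out_path, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: total=%d adapter_matched=%d too_short=%d ",
                     "low_quality=%d passed=%d\n"),
              x$total, x$adapter_matched, x$too_short, x$low_quality, x$passed))
  invisible(x)
}

#' @rdname preprocess_fastq
#' @param report a `qc_report`.
#' @param path output TSV path.
#' @export
write_qc_report <- function(report, path) {
  write_tsv(as.data.frame(unclass(report)), path,
            header = provenance_header())
}

# Phred+33 FASTQ reader/writer over Biostrings. Returns parallel character
# vectors (id, seq, qual); parse errors are surfaced with the offending file.
read_fastq <- function(path) {
  # the constructor warns while moving the qualities out of the metadata
  # columns; nothing is lost
  x <- tryCatch(suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  list(id = sub("[ \t].*$", "", names(x)),
       seq = toupper(as.character(x)),
       qual = as.character(Biostrings::quality(x)))
}

write_fastq <- function(id, seq, qual, path) {
  obj <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq), Biostrings::PhredQuality(qual))
  names(obj) <- id
  # the writer warns that (empty) metadata columns are dropped; nothing of
  # ours is lost
  suppressWarnings(
    Biostrings::writeQualityScaledXStringSet(obj, path,
                                             compress = grepl("\\.gz$", path)))
  invisible(path)
}

# Phred integer scores <-> Phred+33 strings.
quals_to_string <- function(quals) {
  intToUtf8(pmin(pmax(quals, 0L), 60L) + 33L)
}
string_to_quals <- function(s) {
  utf8ToInt(s) - 33L
}
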
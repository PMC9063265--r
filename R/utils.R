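# Shared helpers: sequence utilities, seeded-RNG scoping, tRNA name grammar,
# FASTA/TSV I/O conventions.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#' @param x single DNA string (IUPAC letters; case preserved as upper).
#' @return reverse-complemented upper-case string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Parse a GtRNAdb-style tRNA name
#'
#' Names follow `tRNA-{isotype}-{anticodon}-{group}-{copy}` at the individual
#' level, dropping the copy field at the isodecoder level and both numeric
#' fields at the isoacceptor level.
#'
#' @param x character vector of names.
#' @param level `"individual"`, `"isodecoder"` or `"isoacceptor"`.
#' @return data.frame with columns `isotype`, `anticodon`, and (where present)
#'   integer `group` and `copy`.
#' @examples
#' parse_trna_name("tRNA-Ala-AGC-2-1")
#' @export
parse_trna_name <- function(x, level = c("individual", "isodecoder", "isoacceptor")) {
  level <- match.arg(level)
  pat <- switch(level,
    individual  = "^tRNA-([A-Za-z]{3})-([A-Za-z]{3})-([0-9]+)-([0-9]+)$",
    isodecoder  = "^tRNA-([A-Za-z]{3})-([A-Za-z]{3})-([0-9]+)$",
    isoacceptor = "^tRNA-([A-Za-z]{3})-([A-Za-z]{3})$")
  ok <- grepl(pat, x)
  if (!all(ok)) {
    stop("unparseable ", level, " tRNA name(s): ",
         paste(utils::head(x[!ok], 3L), collapse = ", "))
  }
  out <- data.frame(isotype = sub(pat, "\\1", x), anticodon = sub(pat, "\\2", x),
                    stringsAsFactors = FALSE)
  if (level != "isoacceptor") out$group <- as.integer(sub(pat, "\\3", x))
  if (level == "individual") out$copy <- as.integer(sub(pat, "\\4", x))
  out
}

# Drop trailing name fields: individual -> isodecoder -> isoacceptor.
strip_name_field <- function(x) sub("-[0-9]+$", "", x)

#' Read a multi-record FASTA file into a named character vector
#' @param path FASTA file (plain or gzip).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences as 60-column-wrapped FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# Tab-delimited writer with provenance header comment lines ("# key: value").
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(header)) {
    writeLines(paste0("# ", names(header), ": ", unlist(header)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

provenance_header <- function(params = list(), seed = NULL) {
  h <- c(tool = paste0("trnaquant ", as.character(utils::packageVersion("trnaquant"))))
  if (length(params)) {
    h <- c(h, params = paste(names(params), unlist(params), sep = "=", collapse = "; "))
  }
  if (!is.null(seed)) h <- c(h, seed = as.character(seed))
  h
}
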
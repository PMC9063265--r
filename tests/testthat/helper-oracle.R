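# Independent brute-force alignment oracle: full Hamming scan over every
# end-to-end placement on both strands of every reference. Kept free of the
# package's aligner internals so it can certify them.

oracle_encode <- function(s, read = FALSE) {
  m <- match(strsplit(toupper(s), "")[[1L]], c("A", "C", "G", "T"))
  # ref ambiguity -> 5, read ambiguity -> 6: never equal to anything
  ifelse(is.na(m), if (read) 6L else 5L, m)
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(s), "")[[1L]]),
                               collapse = ""))
}

# All placements of `read` with mismatches <= k: data.frame
# (ref_name, pos, strand, mismatches); attr "best" = min mismatches or NA.
oracle_hits <- function(refs, read, k = 3L) {
  w <- nchar(read)
  out <- list()
  for (rn in names(refs)) {
    rf <- oracle_encode(refs[[rn]])
    L <- length(rf)
    if (L < w) next
    np <- L - w + 1L
    idx <- outer(seq_len(np) - 1L, seq_len(w), "+")
    win <- matrix(rf[idx], np, w)
    for (st in c("+", "-")) {
      q <- oracle_encode(if (st == "+") read else oracle_revcomp(read),
                         read = TRUE)
      mm <- rowSums(win != matrix(q, np, w, byrow = TRUE))
      keep <- which(mm <= k)
      if (length(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          ref_name = rn, pos = keep - 1L, strand = st,
          mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else {
    data.frame(ref_name = character(0), pos = integer(0),
               strand = character(0), mismatches = integer(0))
  }
  attr(hits, "best") <- if (nrow(hits)) min(hits$mismatches) else NA_integer_
  hits
}

# Hamming distance of the oriented read against the reference window.
oracle_distance_at <- function(refs, read, ref_name, pos, strand) {
  w <- nchar(read)
  window <- substr(refs[[ref_name]], pos + 1L, pos + w)
  q <- if (strand == "+") read else oracle_revcomp(read)
  a <- oracle_encode(window)
  b <- oracle_encode(q, read = TRUE)
  sum(a != b)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a read at `positions` (1-based) to a different base.
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
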
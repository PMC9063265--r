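# Parsing tRNAscan-SE tabular output and GtRNAdb-style gene naming.
#
# tRNAscan-SE coordinates are 1-based inclusive with begin > end encoding the
# minus strand; everything downstream of the parser uses 0-based half-open
# coordinates on the + reference frame.

MITO_CHROM_PATTERN <- "^(chrM|chrMT|MT|mito)"

#' Parse tRNAscan-SE tabular annotation
#'
#' Consumes the tRNAscan-SE tabular dialect: columns sequence name, tRNA
#' number, begin, end, isotype, anticodon, intron begin, intron end, score and
#' an optional note. Header lines beginning with `Sequence`, `Name` or `----`
#' are skipped. Intron fields are 0 when absent; comma-separated lists are
#' accepted for multi-intron genes.
#'
#' @param annotation path to a file, or a character vector of lines.
#' @param genome named character vector of chromosome sequences (used to
#'   validate names and bounds).
#' @return data.frame of genes with columns `name` (NA until
#'   [assign_gtrnadb_names()]), `chrom`, `start`, `end` (0-based half-open, +
#'   frame), `strand`, `isotype`, `anticodon`, list columns `intron_starts` /
#'   `intron_ends` (gene-local, half-open, post-orientation), `score`,
#'   `pseudo`, `high_confidence`, `cytosolic`.
#' @details A gene is flagged non-cytosolic when its chromosome name matches a
#'   mitochondrial pattern (`chrM`, `chrMT`, `MT`, `mito`, case-insensitive).
#'   `pseudo` is set when the note contains "pseudo"; `high_confidence` when
#'   it contains "high confidence", or for every non-pseudo gene when the
#'   table carries no note column at all.
#' @export
parse_trna_annotation <- function(annotation, genome) {
  lines <- if (length(annotation) == 1L && file.exists(annotation)) {
    readLines(annotation)
  } else {
    as.character(annotation)
  }
  keep <- !grepl("^(Sequence|Name|----)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(empty_gene_table())
  }
  rows <- strsplit(trimws(lines[idx]), "[ \t]+")
  n_fields <- vapply(rows, length, 0L)
  if (any(n_fields < 9L)) {
    stop("annotation line ", idx[which(n_fields < 9L)[1L]],
         ": expected at least 9 whitespace-separated fields")
  }
  has_note <- any(n_fields >= 10L)

  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    line_no <- idx[i]
    chrom <- f[1L]
    if (!chrom %in% names(genome)) {
      stop("annotation line ", line_no, ": chromosome '", chrom,
           "' absent from genome")
    }
    begin <- suppressWarnings(as.numeric(f[3L]))
    end1 <- suppressWarnings(as.numeric(f[4L]))
    score <- suppressWarnings(as.numeric(f[9L]))
    if (anyNA(c(begin, end1, score))) {
      stop("annotation line ", line_no, ": non-numeric coordinate or score")
    }
    if (begin == end1) {
      stop("annotation line ", line_no, ": begin == end")
    }
    isotype <- f[5L]
    anticodon <- toupper(f[6L])
    if (nchar(anticodon) != 3L) {
      stop("annotation line ", line_no, ": anticodon '", anticodon,
           "' is not length 3")
    }
    strand <- if (begin < end1) "+" else "-"
    start0 <- min(begin, end1) - 1
    end0 <- max(begin, end1)
    if (start0 < 0 || end0 > nchar(genome[[chrom]])) {
      stop("annotation line ", line_no, ": coordinates outside chromosome")
    }
    ib <- suppressWarnings(as.numeric(strsplit(f[7L], ",")[[1L]]))
    ie <- suppressWarnings(as.numeric(strsplit(f[8L], ",")[[1L]]))
    if (anyNA(ib) || anyNA(ie) || length(ib) != length(ie)) {
      stop("annotation line ", line_no, ": malformed intron fields")
    }
    present <- ib != 0 & ie != 0
    ib <- ib[present]; ie <- ie[present]
    gene_len <- end0 - start0
    if (length(ib)) {
      if (strand == "+") {
        loc_s <- ib - begin
        loc_e <- ie - begin + 1
      } else {
        loc_s <- begin - ib
        loc_e <- begin - ie + 1
      }
      bad <- loc_s < 0 | loc_e > gene_len | loc_s >= loc_e
      if (any(bad)) {
        stop("annotation line ", line_no, ": intron outside gene span")
      }
      o <- order(loc_s)
      loc_s <- loc_s[o]; loc_e <- loc_e[o]
      if (length(loc_s) > 1L && any(loc_s[-1L] < loc_e[-length(loc_e)])) {
        stop("annotation line ", line_no, ": overlapping introns")
      }
    } else {
      loc_s <- numeric(0)
      loc_e <- numeric(0)
    }
    note <- if (n_fields[i] >= 10L) paste(f[10:n_fields[i]], collapse = " ") else ""
    pseudo <- grepl("pseudo", note, ignore.case = TRUE)
    high_conf <- if (has_note) {
      grepl("high[ _]confidence", note, ignore.case = TRUE)
    } else {
      !pseudo
    }
    out[[i]] <- list(chrom = chrom, start = start0, end = end0, strand = strand,
                     isotype = isotype, anticodon = anticodon,
                     intron_starts = loc_s, intron_ends = loc_e,
                     score = score, pseudo = pseudo, high_confidence = high_conf)
  }

  genes <- data.frame(
    name = NA_character_,
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    isotype = vapply(out, `[[`, "", "isotype"),
    anticodon = vapply(out, `[[`, "", "anticodon"),
    score = vapply(out, `[[`, 0, "score"),
    pseudo = vapply(out, `[[`, NA, "pseudo"),
    high_confidence = vapply(out, `[[`, NA, "high_confidence"),
    stringsAsFactors = FALSE)
  genes$intron_starts <- I(lapply(out, `[[`, "intron_starts"))
  genes$intron_ends <- I(lapply(out, `[[`, "intron_ends"))
  genes$cytosolic <- !grepl(MITO_CHROM_PATTERN, genes$chrom, ignore.case = TRUE)
  genes
}

empty_gene_table <- function() {
  data.frame(name = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), strand = character(0), isotype = character(0),
             anticodon = character(0), score = numeric(0), pseudo = logical(0),
             high_confidence = logical(0),
             intron_starts = I(list()), intron_ends = I(list()),
             cytosolic = logical(0), stringsAsFactors = FALSE)
}

#' Assign GtRNAdb-style names to parsed tRNA genes
#'
#' Genes sharing (isotype, anticodon, spliced mature sequence) form one
#' sequence group; the name is `tRNA-{isotype}-{anticodon}-{group}-{copy}`.
#' Groups are numbered within each (isotype, anticodon) family by descending
#' maximum score, ties broken by lexicographic mature sequence; copies within
#' a group are numbered by (chromosome, start) ascending. Pre-existing
#' (non-NA) names are preserved verbatim.
#'
#' @param genes data.frame from [parse_trna_annotation()].
#' @param genome named character vector of chromosome sequences.
#' @return `genes` with the `name` column filled in.
#' @export
assign_gtrnadb_names <- function(genes, genome) {
  if (!nrow(genes)) return(genes)
  mature <- vapply(seq_len(nrow(genes)), function(i) {
    extract_mature_sequence(genes[i, ], genome)
  }, "")
  fam <- paste(genes$isotype, genes$anticodon, sep = "-")
  group <- integer(nrow(genes))
  copy <- integer(nrow(genes))
  for (f in unique(fam)) {
    sel <- which(fam == f)
    max_score <- tapply(genes$score[sel], mature[sel], max)
    seqs <- names(max_score)
    seqs <- seqs[order(-max_score, seqs)]
    gid <- match(mature[sel], seqs)
    group[sel] <- gid
    for (g in unique(gid)) {
      members <- sel[gid == g]
      o <- order(genes$chrom[members], genes$start[members])
      copy[members[o]] <- seq_along(members)
    }
  }
  new_names <- sprintf("tRNA-%s-%s-%d-%d", genes$isotype, genes$anticodon,
                       group, copy)
  genes$name <- ifelse(is.na(genes$name), new_names, genes$name)
  genes
}
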
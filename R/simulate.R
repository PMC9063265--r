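# Synthetic data with known ground truth: toy genomes with planted tRNA
# genes (emitted in the tRNAscan-SE tabular dialect the parser consumes) and
# small-RNA read sets with per-read origin labels and per-gene true counts.
#
# Genes are planted in the right half of each chromosome; background
# (non-tRNA) reads are drawn from the left half, at least 1 kb from any
# gene, so their true class is unambiguous.

SIM_ISOTYPES <- list(
  Ala = c("AGC", "CGC", "TGC"), Arg = c("ACG", "CCG", "TCT"),
  Asn = c("GTT"), Asp = c("GTC"), Cys = c("GCA"),
  Gln = c("CTG", "TTG"), Glu = c("CTC", "TTC"), Gly = c("GCC", "CCC"),
  His = c("GTG"), Ile = c("AAT", "GAT"), Leu = c("AAG", "CAG", "TAG"),
  Lys = c("CTT", "TTT"), Met = c("CAT"), Phe = c("GAA"),
  Pro = c("AGG", "TGG"), Ser = c("AGA", "GCT"), Thr = c("AGT", "TGT"),
  Trp = c("CCA"), Tyr = c("GTA"), Val = c("AAC", "TAC"))

#' Simulation configuration
#'
#' Defaults describe a small but realistic study: a two-chromosome 10 kb toy
#' genome with a dozen planted tRNA genes (some sequence-identical copies,
#' some with introns, some pseudogenes), log-normal gene abundances, reads
#' of 18-45 nt with a 0.5% per-base substitution rate, and a 70/15/15
#' mature/premature/background read mixture.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in nt (>= 4000).
#' @param n_genes planted tRNA genes (spread across chromosomes).
#' @param gene_len_range genomic gene-span length range, nt.
#' @param intron_prob per-gene intron probability.
#' @param intron_len_range intron length range, nt.
#' @param frac_minus fraction of genes on the minus strand.
#' @param frac_pseudo fraction annotated as pseudogenes.
#' @param n_mito_genes genes planted on an extra `chrM` chromosome
#'   (non-cytosolic), default 0.
#' @param dup_fraction fraction of genes planted as exact sequence copies of
#'   an earlier gene (exercises isodecoder grouping).
#' @param gc background GC content.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance sampler.
#' @param n_reads total simulated reads.
#' @param origin_fracs named fractions for `mature`, `premature`,
#'   `non_trna`; must sum to 1.
#' @param read_len_range read length range, nt.
#' @param frac_3p fraction of mature-origin reads anchored at the 3' end
#'   (covering the CCA tail).
#' @param interior_only when TRUE, mature-origin fragments never overlap the
#'   appended CCA (start positions confined to the gene body); used for
#'   exact-recovery experiments where CCA-straddling reads are a known,
#'   documented loss mode. Overrides `frac_3p`.
#' @param error_rate per-base substitution rate.
#' @param adapter 3' adapter sequence appended to short inserts (NULL for
#'   none).
#' @param adapter_prob probability a short insert reads through into the
#'   adapter.
#' @param machine_len sequencer read length (cycles).
#' @param qual_mean,qual_sd Phred quality profile.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len = 10000L, n_genes = 12L,
                       gene_len_range = c(70L, 90L), intron_prob = 0.2,
                       intron_len_range = c(10L, 20L), frac_minus = 0.5,
                       frac_pseudo = 0.1, n_mito_genes = 0L,
                       dup_fraction = 0.2, gc = 0.5,
                       abundance_meanlog = log(100), abundance_sdlog = 1,
                       n_reads = 10000L,
                       origin_fracs = c(mature = 0.7, premature = 0.15,
                                        non_trna = 0.15),
                       read_len_range = c(18L, 45L), frac_3p = 0.5,
                       interior_only = FALSE,
                       error_rate = 0.005, adapter = NULL, adapter_prob = 1,
                       machine_len = 50L, qual_mean = 37, qual_sd = 2,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(chrom_len >= 4000, n_chroms >= 1,
            all(origin_fracs >= 0), abs(sum(origin_fracs) - 1) < 1e-8,
            all(c("mature", "premature", "non_trna") %in% names(origin_fracs)),
            frac_3p >= 0, frac_3p <= 1, error_rate >= 0, error_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

sample_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a toy genome with planted tRNA genes
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector), `annotation`
#'   (character vector of tRNAscan-SE-format lines) and `truth` (data.frame
#'   of planted gene coordinates, strands and oriented sequences).
#'   Deterministic per seed.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- stats::setNames(
      vapply(chroms, function(x) sample_bases(cfg$chrom_len, cfg$gc), ""),
      chroms)
    plan <- data.frame(chrom = rep(chroms, length.out = cfg$n_genes),
                       stringsAsFactors = FALSE)
    if (cfg$n_mito_genes > 0) {
      genome <- c(genome, chrM = sample_bases(max(4000L, cfg$chrom_len %/% 2L),
                                              cfg$gc))
      plan <- rbind(plan, data.frame(chrom = rep("chrM", cfg$n_mito_genes)))
    }
    n_total <- nrow(plan)
    if (!n_total) {
      return(list(genome = genome, annotation = character(0),
                  truth = data.frame()))
    }

    gene_seq <- character(n_total)
    intron_s <- vector("list", n_total)
    intron_e <- vector("list", n_total)
    isotype <- character(n_total)
    anticodon <- character(n_total)
    for (i in seq_len(n_total)) {
      if (i > 1 && stats::runif(1) < cfg$dup_fraction) {
        j <- sample.int(i - 1L, 1L)
        gene_seq[i] <- gene_seq[j]
        intron_s[[i]] <- intron_s[[j]]
        intron_e[[i]] <- intron_e[[j]]
        isotype[i] <- isotype[j]
        anticodon[i] <- anticodon[j]
        next
      }
      g_len <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]), 1L)
      if (stats::runif(1) < cfg$intron_prob) {
        i_len <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]), 1L)
        i_start <- sample(seq(5L, g_len - i_len - 5L), 1L)
        intron_s[[i]] <- i_start
        intron_e[[i]] <- i_start + i_len
      } else {
        intron_s[[i]] <- integer(0)
        intron_e[[i]] <- integer(0)
      }
      gene_seq[i] <- sample_bases(g_len, cfg$gc)
      iso <- sample(names(SIM_ISOTYPES), 1L)
      isotype[i] <- iso
      anticodon[i] <- sample(SIM_ISOTYPES[[iso]], 1L)
    }

    # pack genes into the right half of each chromosome, >= 20 nt apart
    start <- integer(n_total)
    end <- integer(n_total)
    for (ch in unique(plan$chrom)) {
      sel <- which(plan$chrom == ch)
      L <- nchar(genome[[ch]])
      cursor <- L %/% 2L
      for (i in sel) {
        g_len <- nchar(gene_seq[i])
        # keep neighbors farther apart than the 50 nt decoy flank so no
        # decoy chromosome swallows a neighboring gene body
        gap <- 60L + sample.int(60L, 1L)
        start[i] <- cursor + gap
        end[i] <- start[i] + g_len
        cursor <- end[i]
      }
      if (cursor > L - 100L) {
        stop("infeasible packing: genes do not fit chromosome ", ch)
      }
    }

    strand <- ifelse(stats::runif(n_total) < cfg$frac_minus, "-", "+")
    pseudo <- stats::runif(n_total) < cfg$frac_pseudo
    score <- round(stats::runif(n_total, 50, 100), 1)

    ann <- character(n_total)
    for (i in seq_len(n_total)) {
      planted <- if (strand[i] == "+") gene_seq[i] else revcomp(gene_seq[i])
      substr(genome[[plan$chrom[i]]], start[i] + 1L, end[i]) <- planted
      b1 <- start[i] + 1L
      e1 <- end[i]
      if (strand[i] == "+") {
        begin <- b1; endc <- e1
      } else {
        begin <- e1; endc <- b1
      }
      if (length(intron_s[[i]])) {
        s <- intron_s[[i]][1L]; e <- intron_e[[i]][1L]
        if (strand[i] == "+") {
          ib <- begin + s; ie <- begin + e - 1L
        } else {
          ib <- begin - s; ie <- begin - e + 1L
        }
      } else {
        ib <- 0L; ie <- 0L
      }
      note <- if (pseudo[i]) "pseudo" else "high confidence set"
      ann[i] <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%.1f\t%s",
                        plan$chrom[i], i, begin, endc, isotype[i],
                        anticodon[i], ib, ie, score[i], note)
    }
    truth <- data.frame(chrom = plan$chrom, start = start, end = end,
                        strand = strand, isotype = isotype,
                        anticodon = anticodon, pseudo = pseudo,
                        score = score, gene_seq = gene_seq,
                        stringsAsFactors = FALSE)
    truth$intron_starts <- I(intron_s)
    truth$intron_ends <- I(intron_e)
    list(genome = genome, annotation = ann, truth = truth)
  })
}

#' Simulate small-RNA reads from a genome bundle
#'
#' Mature-origin reads are contiguous fragments of mature sequences (a
#' `frac_3p` share anchored at the 3' end, covering the CCA); premature
#' reads straddle a flank/gene junction of a decoy record; background reads
#' come from the gene-free left half of each chromosome, >= 1 kb from any
#' gene. Substitution errors, optional adapter read-through and Phred
#' qualities are applied per config. Deterministic per seed.
#'
#' @param bundle a `genome_bundle` built from [simulate_genome()] output.
#' @param cfg a [sim_config()].
#' @param abundances optional named true abundances; defaults to a log-normal
#'   draw over the countable genes (cytosolic, high-confidence, non-pseudo).
#' @param fastq optional path; when given, reads are written as FASTQ.
#' @return list with `reads` (named character vector), `quals` (named Phred
#'   strings), `truth` (per-read data.frame: `read_id`, `origin`, `gene`,
#'   `source_ref`, `source_start`, `read_len`), `true_counts` (named integer
#'   vector over countable genes), `abundances`, and `fastq` (path or NULL).
#' @export
simulate_reads <- function(bundle, cfg, abundances = NULL, fastq = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    reg <- bundle$registry
    mat <- reg[reg$role == "mature", , drop = FALSE]
    countable <- mat$gene_name[mat$cytosolic & mat$high_confidence & !mat$pseudo]
    if (is.null(abundances)) {
      abundances <- stats::setNames(
        stats::rlnorm(length(countable), cfg$abundance_meanlog,
                      cfg$abundance_sdlog), countable)
    }
    n_o <- stats::rmultinom(1L, cfg$n_reads,
                            cfg$origin_fracs[c("mature", "premature",
                                               "non_trna")])[, 1L]
    lens <- function(n) sample(seq(cfg$read_len_range[1],
                                   cfg$read_len_range[2]),
                               n, replace = TRUE)

    origin <- character(0); gene <- character(0); src <- character(0)
    src_start <- integer(0); seqs <- character(0)

    if (n_o[1L] > 0) {
      if (!length(abundances) || all(abundances <= 0)) {
        stop("mature reads requested but no positive abundances")
      }
      g <- sample(names(abundances), n_o[1L], replace = TRUE,
                  prob = abundances)
      body_slack <- if (isTRUE(cfg$interior_only)) 3L else 0L
      l <- pmin(lens(n_o[1L]), nchar(bundle$mature[g]) - body_slack)
      anchored <- !isTRUE(cfg$interior_only) &
        stats::runif(n_o[1L]) < cfg$frac_3p
      p <- integer(n_o[1L])
      for (i in seq_len(n_o[1L])) {
        room <- nchar(bundle$mature[[g[i]]]) - body_slack - l[i]
        p[i] <- if (anchored[i]) room + body_slack
                else sample.int(room + 1L, 1L) - 1L
      }
      seqs <- c(seqs, substr(bundle$mature[g], p + 1L, p + l))
      origin <- c(origin, rep("mature", n_o[1L]))
      gene <- c(gene, g); src <- c(src, g); src_start <- c(src_start, p)
    }
    if (n_o[2L] > 0) {
      prem <- bundle$premature
      if (!nrow(prem)) stop("premature reads requested but no genes")
      ridx <- sample.int(nrow(prem), n_o[2L], replace = TRUE)
      l <- lens(n_o[2L])
      p <- integer(n_o[2L])
      for (i in seq_len(n_o[2L])) {
        r <- prem[ridx[i], ]
        rl <- nchar(r$seq)
        l[i] <- min(l[i], rl)
        jn <- c(r$upstream_flank_len, r$upstream_flank_len + r$gene_len)
        jn <- jn[jn > 0 & jn < rl]  # junctions with flank present
        j <- if (length(jn)) sample(rep(jn, 2L), 1L) else r$upstream_flank_len
        lo <- max(0L, j - l[i] + 1L)
        hi <- min(rl - l[i], j - 1L)
        p[i] <- if (hi >= lo) sample(seq(lo, hi), 1L) else lo
      }
      seqs <- c(seqs, substr(prem$seq[ridx], p + 1L, p + l))
      origin <- c(origin, rep("premature", n_o[2L]))
      gene <- c(gene, prem$gene_name[ridx])
      src <- c(src, prem$ref_name[ridx]); src_start <- c(src_start, p)
    }
    if (n_o[3L] > 0) {
      chroms <- names(bundle$masked)
      chroms <- chroms[!grepl(MITO_CHROM_PATTERN, chroms, ignore.case = TRUE)]
      l <- lens(n_o[3L])
      ch <- character(n_o[3L])
      p <- integer(n_o[3L])
      for (i in seq_len(n_o[3L])) {
        draw <- sample_background(bundle, chroms, l[i], margin = 1000L)
        ch[i] <- draw$chrom
        p[i] <- draw$pos
      }
      seqs <- c(seqs, substr(bundle$masked[ch], p + 1L, p + l))
      origin <- c(origin, rep("non_trna", n_o[3L]))
      gene <- c(gene, rep(NA_character_, n_o[3L]))
      src <- c(src, ch); src_start <- c(src_start, p)
    }

    n <- length(seqs)
    ord <- sample.int(n)
    seqs <- unname(seqs[ord]); origin <- origin[ord]; gene <- gene[ord]
    src <- src[ord]; src_start <- src_start[ord]
    ids <- sprintf("sim_%06d", seq_len(n))

    seqs <- vapply(seqs, add_errors, "", error_rate = cfg$error_rate,
                   USE.NAMES = FALSE)
    insert_len <- nchar(seqs)
    if (!is.null(cfg$adapter)) {
      thru <- stats::runif(n) < cfg$adapter_prob
      for (i in which(thru)) {
        full <- paste0(seqs[i], toupper(cfg$adapter))
        seqs[i] <- substr(full, 1L, cfg$machine_len)
      }
    }
    quals <- vapply(nchar(seqs), function(l) {
      quals_to_string(pmin(40L, pmax(2L, round(
        stats::rnorm(l, cfg$qual_mean, cfg$qual_sd)))))
    }, "")

    truth <- data.frame(read_id = ids, origin = origin, gene = gene,
                        source_ref = src, source_start = src_start,
                        insert_len = insert_len, read_len = nchar(seqs),
                        stringsAsFactors = FALSE)
    true_counts <- stats::setNames(integer(length(countable)), countable)
    tc <- table(gene[origin == "mature"])
    keep <- names(tc) %in% countable
    true_counts[names(tc)[keep]] <- as.integer(tc[keep])

    out_path <- NULL
    if (!is.null(fastq)) {
      write_fastq(ids, seqs, quals, fastq)
      out_path <- fastq
    }
    list(reads = stats::setNames(seqs, ids),
         quals = stats::setNames(quals, ids),
         truth = truth, true_counts = true_counts,
         abundances = abundances, fastq = out_path)
  })
}

# Uniform draw of a background read start >= `margin` nt away from every
# annotated gene, from the gene-free complement of the listed chromosomes.
sample_background <- function(bundle, chroms, len, margin = 1000L) {
  allowed <- list()
  for (ch in chroms) {
    L <- nchar(bundle$masked[[ch]])
    hi <- L - len
    if (hi < 0L) next
    g <- bundle$genes[bundle$genes$chrom == ch, , drop = FALSE]
    # forbidden start range per gene: read must end margin nt before the
    # gene or start margin nt after it
    lo_f <- g$start - margin - len + 1L
    hi_f <- g$end + margin - 1L
    o <- order(lo_f)
    lo_f <- lo_f[o]; hi_f <- hi_f[o]
    cur <- 0L
    for (j in seq_along(lo_f)) {
      if (lo_f[j] > cur) {
        allowed[[length(allowed) + 1L]] <-
          list(chrom = ch, lo = cur, hi = min(lo_f[j] - 1L, hi))
      }
      cur <- max(cur, hi_f[j] + 1L)
    }
    if (cur <= hi) {
      allowed[[length(allowed) + 1L]] <- list(chrom = ch, lo = cur, hi = hi)
    }
  }
  allowed <- Filter(function(a) a$hi >= a$lo, allowed)
  if (!length(allowed)) {
    stop("no background region >= ", margin, " nt away from all genes")
  }
  sizes <- vapply(allowed, function(a) as.numeric(a$hi - a$lo + 1), 0)
  k <- sample.int(length(allowed), 1L, prob = sizes)
  pick <- allowed[[k]]
  list(chrom = pick$chrom,
       pos = as.integer(pick$lo + sample.int(sizes[k], 1L) - 1L))
}

# Per-base substitution errors (to a uniformly chosen different base).
add_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  l <- nchar(seq)
  n_err <- stats::rbinom(1L, l, error_rate)
  if (!n_err) return(seq)
  pos <- sample.int(l, n_err)
  chars <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
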
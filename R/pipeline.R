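# End-to-end orchestration: genome build -> preprocessing -> two-round
# quantification -> prevalence filter -> DE per level -> plot data, with
# tab-delimited artifacts and a JSON-lines run log.

#' Pipeline configuration
#'
#' @param genome path to the genome FASTA, or a named character vector.
#' @param annotation path to the tRNAscan-SE tabular annotation, or lines.
#' @param samples data.frame with columns `sample`, `fastq`, `group`
#'   (exactly two groups for the DE stage).
#' @param out_dir output directory.
#' @param flank_len premature flank length (default 50).
#' @param preprocess a [preprocess_params()] object.
#' @param k aligner mismatch budget (default 3).
#' @param seed aligner tie-break seed (default 1715), recorded in all
#'   provenance headers.
#' @param len_threshold non-tRNA carry-forward bound (default 30).
#' @param min_cpm,min_fraction prevalence filter (defaults 1 and 0.9).
#' @param fc_threshold,alpha,adjust DE significance parameters.
#' @param top_k MDS leading-logFC window (default 500).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, samples, out_dir,
                            flank_len = 50L,
                            preprocess = preprocess_params(),
                            k = 3L, seed = 1715L, len_threshold = 30L,
                            min_cpm = 1, min_fraction = 0.9,
                            fc_threshold = 1.5, alpha = 0.05, adjust = "bh",
                            top_k = 500L) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "fastq", "group") %in% names(samples)))
  missing_fq <- samples$fastq[!file.exists(samples$fastq)]
  if (length(missing_fq)) {
    stop("missing FASTQ file(s): ", paste(missing_fq, collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

log_event <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Chains every stage in workflow order and writes all artifacts (count
#' matrices at the three levels, QC and class-tally tables, DE tables, plot
#' data) as tab-delimited text under `cfg$out_dir`, plus `run_log.jsonl`.
#' Reruns with identical inputs and seed produce identical tables.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the in-memory results of each stage, invisibly the
#'   artifact paths in `$paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  hdr <- provenance_header(list(k = cfg$k, len_threshold = cfg$len_threshold),
                           seed = cfg$seed)

  genome <- if (is.character(cfg$genome) && length(cfg$genome) == 1L &&
                file.exists(cfg$genome)) read_fasta(cfg$genome) else cfg$genome
  genes <- parse_trna_annotation(cfg$annotation, genome)
  genes <- assign_gtrnadb_names(genes, genome)
  bundle <- build_bundle(genome, genes, cfg$flank_len)
  write_bundle(bundle, file.path(cfg$out_dir, "genome"))
  log_event(log_path, "build_genome", n_genes = nrow(genes),
            flank_len = cfg$flank_len)

  qc <- list()
  clean <- character(nrow(cfg$samples))
  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples$sample[i]
    clean[i] <- file.path(cfg$out_dir, paste0(s, ".clean.fastq"))
    res <- preprocess_fastq(cfg$samples$fastq[i], clean[i], cfg$preprocess)
    qc[[s]] <- res$report
    log_event(log_path, "preprocess", sample = s,
              report = unclass(res$report))
  }
  qc_df <- do.call(rbind, lapply(names(qc), function(s) {
    cbind(data.frame(sample = s), as.data.frame(unclass(qc[[s]])))
  }))
  write_tsv(qc_df, file.path(cfg$out_dir, "qc_report.tsv"), header = hdr)

  quant <- quantify_samples(stats::setNames(clean, cfg$samples$sample),
                            bundle, k = cfg$k, seed = cfg$seed,
                            len_threshold = cfg$len_threshold)
  counts <- list(individual = quant$counts,
                 isodecoder = aggregate_counts(quant$counts, "isodecoder"),
                 isoacceptor = aggregate_counts(quant$counts, "isoacceptor"))
  for (lv in names(counts)) {
    write_tsv(data.frame(name = rownames(counts[[lv]]), counts[[lv]],
                         check.names = FALSE),
              file.path(cfg$out_dir, paste0("counts_", lv, ".tsv")),
              header = hdr)
  }
  write_tsv(data.frame(sample = rownames(quant$tallies), quant$tallies,
                       check.names = FALSE),
            file.path(cfg$out_dir, "class_tally.tsv"), header = hdr)
  log_event(log_path, "quantify", samples = nrow(cfg$samples),
            genes = nrow(quant$counts))

  group <- factor(cfg$samples$group)
  de <- list()
  mds <- NULL
  for (lv in names(counts)) {
    filt <- filter_low_counts(counts[[lv]], cfg$min_cpm, cfg$min_fraction)
    write_tsv(data.frame(name = rownames(filt$kept), filt$kept,
                         check.names = FALSE),
              file.path(cfg$out_dir, paste0("filtered_", lv, ".tsv")),
              header = hdr)
    if (nrow(filt$kept) < 2L || nlevels(droplevels(group)) != 2L) {
      log_event(log_path, "de_skipped", level = lv,
                kept = nrow(filt$kept))
      next
    }
    de[[lv]] <- run_de(filt$kept, group, cfg$fc_threshold, cfg$alpha,
                       cfg$adjust)
    write_de_table(de[[lv]],
                   file.path(cfg$out_dir, paste0("de_", lv, ".tsv")),
                   level = lv)
    log_event(log_path, "de", level = lv, tested = nrow(de[[lv]]),
              significant = sum(de[[lv]]$significant))
    if (lv == "individual" && ncol(filt$kept) >= 3L) {
      f <- attr(de[[lv]], "tmm_factors")
      lcpm <- log2(cpm_matrix(filt$kept, colSums(filt$kept) * f) + 0.5)
      mds <- mds_coordinates(lcpm, cfg$top_k)
      write_tsv(data.frame(sample = rownames(mds$coords), mds$coords,
                           group = as.character(group)),
                file.path(cfg$out_dir, "mds.tsv"), header = hdr)
    }
  }
  if (!is.null(de$individual)) {
    write_tsv(volcano_data(de$individual, cfg$fc_threshold, cfg$alpha),
              file.path(cfg$out_dir, "volcano.tsv"), header = hdr)
  }
  if (!is.null(de$isodecoder)) {
    write_tsv(anticodon_bar_data(de$isodecoder),
              file.path(cfg$out_dir, "anticodon_bar.tsv"), header = hdr)
  }
  if (!is.null(de$isoacceptor)) {
    write_tsv(aa_pyramid_data(de$isoacceptor),
              file.path(cfg$out_dir, "aa_pyramid.tsv"), header = hdr)
  }
  log_event(log_path, "done")
  invisible(list(bundle = bundle, qc = qc, counts = counts,
                 tallies = quant$tallies, de = de, mds = mds,
                 paths = list(out_dir = cfg$out_dir, log = log_path)))
}
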
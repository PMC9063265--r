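# Two-round classification, counting and aggregation.

fake_hit <- function(ref, pos, len, id = "r1") {
  data.frame(read_id = id, ref_name = ref, pos = pos, strand = "+",
             mismatches = 0L, read_len = len, stringsAsFactors = FALSE)
}

test_that("classes follow the mapping location", {
  bundle <- make_toy_bundle()
  reg <- bundle$registry
  prem_ref <- bundle$premature$ref_name[1]
  uf <- bundle$premature$upstream_flank_len[1]
  gl <- bundle$premature$gene_len[1]

  expect_equal(classify_first_round(fake_hit("chr1", 10, 30), reg),
               "non_trna")
  expect_equal(classify_first_round(fake_hit(prem_ref, uf, gl), reg),
               "mature")
  expect_equal(classify_first_round(fake_hit(prem_ref, uf - 1, 30), reg),
               "premature")
  unmapped <- fake_hit(NA_character_, NA_integer_, 30)
  expect_equal(classify_first_round(unmapped, reg), "unmapped")
  expect_error(classify_first_round(fake_hit("nonsense", 0, 10), reg),
               "unknown")
})

test_that("the class flips from premature to mature exactly at containment", {
  bundle <- make_toy_bundle()
  reg <- bundle$registry
  prem_ref <- bundle$premature$ref_name[1]
  uf <- bundle$premature$upstream_flank_len[1]   # 50
  gl <- bundle$premature$gene_len[1]             # 72
  len <- 30L
  for (pos in seq(uf - 5, uf + gl - len + 5)) {
    cls <- classify_first_round(fake_hit(prem_ref, pos, len), reg)
    inside <- pos >= uf && pos + len <= uf + gl
    expect_equal(cls, if (inside) "mature" else "premature",
                 info = paste("pos", pos))
  }
})

test_that("second-round selection takes mature plus short non-tRNA reads", {
  classes <- c("mature", "mature", "non_trna", "non_trna", "premature",
               "unmapped")
  lens <- c(45L, 18L, 29L, 30L, 20L, 25L)
  expect_equal(select_second_round(classes, lens),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("counting covers included genes only and reports drops", {
  bundle <- make_toy_bundle()
  included <- with(subset(bundle$registry, role == "mature"),
                   gene_name[cytosolic & high_confidence & !pseudo])
  pseudo_gene <- with(subset(bundle$registry, role == "mature"),
                      gene_name[pseudo])[1]
  hits <- rbind(fake_hit(included[1], 0, 20, "a1"),
                fake_hit(included[1], 5, 20, "a2"),
                fake_hit(included[1], 9, 20, "a3"),
                fake_hit(pseudo_gene, 0, 20, "p1"))
  res <- count_individual(hits, bundle$registry)
  expect_setequal(names(res$counts), included)
  expect_equal(unname(res$counts[included[1]]), 3L)
  expect_equal(res$drop_report$gene, pseudo_gene)
  expect_equal(res$drop_report$reads, 1L)
  # zero hits give an all-zero table over the same universe
  zero <- count_individual(hits[0, ], bundle$registry)
  expect_equal(sum(zero$counts), 0L)
  expect_setequal(names(zero$counts), included)
})

test_that("the printed worked example aggregates 551 + 560 = 1111", {
  counts <- matrix(c(551L, 560L), ncol = 1,
                   dimnames = list(c("tRNA-Ala-AGC-2-1", "tRNA-Ala-AGC-2-2"),
                                   "case"))
  iso <- aggregate_counts(counts, "isodecoder")
  expect_equal(unname(iso["tRNA-Ala-AGC-2", "case"]), 1111L)
})

test_that("aggregation sums per key and conserves column totals", {
  counts <- matrix(c(10L, 1111L, 7L, 3L, 20L, 30L, 1L, 2L), ncol = 2,
                   dimnames = list(c("tRNA-Ala-AGC-1-1", "tRNA-Ala-AGC-2-1",
                                     "tRNA-Ala-TGC-1-1", "tRNA-Gly-GCC-1-1"),
                                   c("s1", "s2")))
  iso <- aggregate_counts(counts, "isodecoder")
  acc <- aggregate_counts(counts, "isoacceptor")
  expect_equal(unname(acc["tRNA-Ala-AGC", "s1"]), 10L + 1111L)
  expect_equal(colSums(iso), colSums(counts))
  expect_equal(colSums(acc), colSums(counts))
  expect_equal(rownames(acc), sort(rownames(acc)))
  # isodecoder tables can be further merged to isoacceptors
  expect_equal(aggregate_counts(iso, "isoacceptor"), acc)
  # empty in, empty out
  expect_equal(nrow(aggregate_counts(counts[0, , drop = FALSE],
                                     "isodecoder")), 0)
  expect_error(aggregate_counts(matrix(1L, dimnames = list("foo", "s")),
                                "isodecoder"), "not parseable")
})

test_that("every read gets exactly one class and tallies partition the input", {
  bundle <- make_toy_bundle()
  cfg <- sim_config(seed = 101, n_reads = 600, n_genes = 4,
                    error_rate = 0.01)
  sim <- simulate_reads(bundle, cfg)
  q <- quantify_sample(sim$reads, bundle)
  t <- q$tally
  expect_equal(t[["n_unmapped"]] + t[["n_non_trna"]] + t[["n_premature"]] +
                 t[["n_mature_r1"]], t[["n_input"]])
  expect_equal(t[["n_input"]], length(sim$reads))
  expect_true(all(q$classes$class %in% c("unmapped", "non_trna",
                                         "premature", "mature")))
})

test_that("error-free interior mature reads are recovered exactly", {
  set.seed(55)
  # unique-sequence, intron-free genes so every interior read is unambiguous
  cfg <- sim_config(seed = 77, n_reads = 1500, n_genes = 8,
                    intron_prob = 0, dup_fraction = 0, frac_pseudo = 0,
                    error_rate = 0, interior_only = TRUE,
                    origin_fracs = c(mature = 1, premature = 0, non_trna = 0))
  sim <- simulate_genome(cfg)
  genes <- assign_gtrnadb_names(parse_trna_annotation(sim$annotation,
                                                      sim$genome), sim$genome)
  bundle <- build_bundle(sim$genome, genes)
  rd <- simulate_reads(bundle, cfg)
  q <- quantify_sample(rd$reads, bundle)
  expect_equal(q$counts[names(rd$true_counts)], rd$true_counts)
  expect_equal(q$tally[["n_counted_r2"]], length(rd$reads))
})

test_that("background-only reads yield zero counts", {
  bundle <- make_toy_bundle()
  cfg <- sim_config(seed = 88, n_reads = 300, n_genes = 4, error_rate = 0,
                    read_len_range = c(30L, 40L),
                    origin_fracs = c(mature = 0, premature = 0, non_trna = 1))
  rd <- simulate_reads(bundle, cfg)
  q <- quantify_sample(rd$reads, bundle)
  expect_equal(sum(q$counts), 0L)
  expect_equal(q$tally[["n_non_trna"]], length(rd$reads))
})

test_that("premature-only reads are excluded from counting", {
  bundle <- make_toy_bundle()
  cfg <- sim_config(seed = 99, n_reads = 300, n_genes = 4, error_rate = 0,
                    origin_fracs = c(mature = 0, premature = 1, non_trna = 0))
  rd <- simulate_reads(bundle, cfg)
  q <- quantify_sample(rd$reads, bundle)
  expect_equal(sum(q$counts), 0L)
  expect_equal(q$tally[["n_premature"]], length(rd$reads))
})

test_that("identical gene copies split reads binomially at individual level", {
  # the toy bundle's two Ala-AGC copies share one mature sequence
  bundle <- make_toy_bundle()
  ala <- grep("tRNA-Ala-AGC-1", names(bundle$mature), value = TRUE)
  expect_length(ala, 2)
  n <- 400L
  mature_seq <- bundle$mature[[ala[1]]]
  reads <- setNames(rep(substr(mature_seq, 11, 40), n),
                    sprintf("dup%03d", seq_len(n)))
  q <- quantify_sample(reads, bundle, seed = 3L)
  total <- sum(q$counts[ala])
  expect_equal(total, n)
  expect_gte(q$counts[[ala[1]]], qbinom(0.005, n, 0.5))
  expect_lte(q$counts[[ala[1]]], qbinom(0.995, n, 0.5))
  # isodecoder aggregation restores the exact total
  iso <- aggregate_counts(q$counts, "isodecoder")
  expect_equal(unname(iso["tRNA-Ala-AGC-1", 1]), n)
})
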
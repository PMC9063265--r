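# Native best-hit aligner vs the brute-force Hamming oracle.

test_that("exact substrings align at their position with zero mismatches", {
  set.seed(41)
  ref <- c(refA = random_dna(300))
  idx <- build_index(ref)
  read <- substr(ref[[1]], 101, 130)
  hit <- align_read(idx, read, read_id = "r+")
  expect_equal(hit$pos, 100)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$strand, "+")

  rc <- oracle_revcomp(substr(ref[[1]], 201, 230))
  hit2 <- align_read(idx, rc, read_id = "r-")
  expect_equal(hit2$pos, 200)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$mismatches, 0)
})

test_that("N never matches on either side", {
  idx <- build_index(c(n_ref = strrep("N", 100)))
  expect_null(align_read(idx, "ACGTACGTACGTACGT"))
  idx2 <- build_index(c(acgt = strrep("ACGT", 30)))
  read_n <- paste0("ACGTACGT", strrep("N", 4), "ACGT")
  hit <- align_read(idx2, read_n, k = 4)
  expect_false(is.null(hit))
  expect_equal(hit$mismatches, 4)  # every N costs one mismatch
})

test_that("planted mismatches up to k are always recovered, never beyond", {
  set.seed(42)
  ref <- c(r1 = random_dna(800))
  idx <- build_index(ref)
  for (j in 0:3) {
    read <- substr(ref[[1]], 301, 335)
    if (j > 0) read <- mutate_at(read, sample(nchar(read), j))
    hit <- align_read(idx, read, k = 3, read_id = sprintf("m%d", j))
    expect_false(is.null(hit))
    expect_lte(hit$mismatches, j)  # planted distance is an upper bound
  }
  read4 <- mutate_at(substr(ref[[1]], 301, 320), 1:6)
  oh <- oracle_hits(ref, read4, k = 3)
  if (!nrow(oh)) expect_null(align_read(idx, read4, k = 3, read_id = "m6"))
})

test_that("reported hits match the brute-force oracle on random instances", {
  set.seed(43)
  for (case in 1:5) {
    refs <- c(a = random_dna(600), b = random_dna(400))
    idx <- build_index(refs)
    reads <- vapply(1:40, function(i) {
      if (runif(1) < 0.7) {
        src <- sample(names(refs), 1)
        p <- sample(nchar(refs[[src]]) - 30, 1)
        r <- substr(refs[[src]], p, p + 29)
        if (runif(1) < 0.5) r <- oracle_revcomp(r)
        mutate_at(r, sample(30, sample(0:3, 1)))
      } else {
        random_dna(30)
      }
    }, "")
    names(reads) <- sprintf("c%d_r%d", case, seq_along(reads))
    hits <- align_batch(idx, reads, k = 3, seed = 7)
    for (i in seq_along(reads)) {
      oh <- oracle_hits(refs, reads[[i]], k = 3)
      if (is.na(hits$ref_name[i])) {
        expect_equal(nrow(oh), 0)
      } else {
        expect_equal(hits$mismatches[i], attr(oh, "best"))
        stratum <- oh[oh$mismatches == attr(oh, "best"), ]
        expect_true(any(stratum$ref_name == hits$ref_name[i] &
                          stratum$pos == hits$pos[i] &
                          stratum$strand == hits$strand[i]))
        # soundness: recomputing the distance at the placement agrees
        expect_equal(oracle_distance_at(refs, reads[[i]], hits$ref_name[i],
                                        hits$pos[i], hits$strand[i]),
                     hits$mismatches[i])
      }
    }
  }
})

test_that("batches are deterministic and order-invariant per read", {
  set.seed(44)
  refs <- c(x = random_dna(500), y = random_dna(500))
  idx <- build_index(refs)
  reads <- setNames(vapply(1:30, function(i) random_dna(25), ""),
                    sprintf("r%02d", 1:30))
  h1 <- align_batch(idx, reads, seed = 5)
  h2 <- align_batch(idx, reads, seed = 5)
  expect_identical(h1, h2)
  perm <- sample(length(reads))
  h3 <- align_batch(idx, reads[perm], seed = 5)
  h3 <- h3[match(h1$read_id, h3$read_id), ]
  rownames(h3) <- NULL
  expect_identical(h1, h3)
})

test_that("tie-breaking is uniform across identical reference copies", {
  set.seed(45)
  core <- random_dna(60)
  refs <- c(copy1 = core, copy2 = core)
  idx <- build_index(refs)
  reads <- setNames(rep(substr(core, 11, 40), 400), sprintf("t%03d", 1:400))
  hits <- align_batch(idx, reads, seed = 2)
  n1 <- sum(hits$ref_name == "copy1")
  # exact binomial 99.9% bounds for p = 0.5, n = 400
  expect_gte(n1, qbinom(0.0005, 400, 0.5))
  expect_lte(n1, qbinom(0.9995, 400, 0.5))
})

test_that("raising k never loses a hit nor worsens the best distance", {
  set.seed(46)
  refs <- c(z = random_dna(700))
  idx <- build_index(refs)
  reads <- setNames(vapply(1:25, function(i) {
    r <- substr(refs[[1]], p <- sample(600, 1), p + 27)
    mutate_at(r, sample(28, sample(0:4, 1)))
  }, ""), sprintf("k%02d", 1:25))
  for (i in seq_along(reads)) {
    prev <- NULL
    for (k in 0:4) {
      hit <- align_read(idx, reads[[i]], k = k, read_id = names(reads)[i])
      if (!is.null(prev)) {
        expect_false(is.null(hit))
        expect_lte(hit$mismatches, prev$mismatches)
      }
      prev <- hit
    }
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(a = "ACGT", a = "ACGT")), "duplicate")
  idx <- build_index(c(a = strrep("ACGT", 10)))
  expect_error(align_batch(idx, c(r1 = "ACG"), k = 3), "shorter")
  expect_error(align_batch(idx, setNames(c("ACGTACGT", "ACGTACGT"),
                                         c("d", "d"))), "duplicate")
  expect_equal(nrow(align_batch(idx, setNames(character(0), character(0)))), 0)
})

test_that("SAM emission carries flags, positions and NM tags", {
  set.seed(47)
  refs <- c(sq = random_dna(200))
  idx <- build_index(refs)
  reads <- c(fwd = substr(refs[[1]], 51, 80),
             rev = oracle_revcomp(substr(refs[[1]], 101, 130)),
             nohit = strrep("N", 30))
  hits <- align_batch(idx, reads, k = 3)
  sam <- withr::local_tempfile(fileext = ".sam")
  hits_to_sam(hits, idx, reads, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:sq\tLN:200", lines)))
  rows <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  flags <- vapply(rows, function(r) as.integer(r[2]), 0L)
  expect_equal(flags, c(0L, 16L, 4L))
  mapped <- rows[flags != 4L]
  expect_equal(vapply(mapped, function(r) as.integer(r[4]), 0L), c(51L, 101L))
  expect_true(all(vapply(mapped, function(r) grepl("NM:i:", r[12]), NA)))
})
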
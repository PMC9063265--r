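# CPM, prevalence filter, TMM, dispersion, exact test, adjustment, run_de.

test_that("CPM is counts over library size times a million", {
  m <- matrix(c(1L, 0L, 551L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_matrix(m, lib_sizes = c(1e6, 2e6))
  expect_equal(cpm["g1", "s1"], 1.0)
  expect_equal(cpm["g2", "s1"], 0.0)
  expect_equal(cpm["g1", "s2"], 275.5)
  expect_error(cpm_matrix(m, lib_sizes = c(0, 1)), "library size")
})

test_that("prevalence filter uses ceiling semantics at the 90% boundary", {
  lib <- rep(1e6, 10)
  mk <- function(n_expressed) {
    counts <- matrix(0L, 2, 10,
                     dimnames = list(c("gene", "anchor"), paste0("s", 1:10)))
    counts["anchor", ] <- 100L                   # keeps lib sizes equal
    counts["gene", seq_len(n_expressed)] <- 10L  # CPM 10 where expressed
    counts
  }
  keep9 <- filter_low_counts(mk(9), min_cpm = 1, min_fraction = 0.9,
                             lib_sizes = lib)
  expect_true("gene" %in% rownames(keep9$kept))
  keep8 <- filter_low_counts(mk(8), min_cpm = 1, min_fraction = 0.9,
                             lib_sizes = lib)
  expect_true("gene" %in% keep8$removed)
  # kept and removed partition the input
  expect_equal(nrow(keep8$kept) + length(keep8$removed), 2)
})

test_that("TMM factors are 1 for identical and globally rescaled columns", {
  set.seed(61)
  a <- rpois(200, 50) + 1L
  ident <- cbind(s1 = a, s2 = a)
  expect_equal(unname(tmm_factors(ident)), c(1, 1))
  doubled <- cbind(s1 = a, s2 = 2L * a)
  expect_equal(unname(tmm_factors(doubled)), c(1, 1))
})

test_that("TMM factors have geometric mean 1 and match edgeR", {
  skip_if_not_installed("edgeR")
  set.seed(62)
  for (i in 1:3) {
    counts <- matrix(rnbinom(300 * 4, mu = 80, size = 5), 300, 4,
                     dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
    counts[1:20, 1] <- counts[1:20, 1] * 8L   # composition bias in s1
    ours <- tmm_factors(counts)
    expect_equal(exp(mean(log(ours))), 1, tolerance = 1e-12)
    theirs <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
  }
})

test_that("TMM is invariant to scaling one column", {
  set.seed(63)
  counts <- matrix(rnbinom(200 * 3, mu = 60, size = 10), 200, 3)
  colnames(counts) <- paste0("s", 1:3)
  f1 <- tmm_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 4L
  f2 <- tmm_factors(scaled)
  # precision weights scale with depth, so invariance is approximate
  expect_equal(unname(f1), unname(f2), tolerance = 0.02)
  expect_error(tmm_factors(counts[, 1, drop = FALSE]), "two samples")
})

test_that("common dispersion recovers Poisson and NB truth", {
  set.seed(64)
  group <- factor(rep(c("a", "b"), each = 3))
  pois <- matrix(rpois(200 * 6, lambda = 100), 200, 6)
  expect_lt(estimate_common_dispersion(pois, group), 0.05)

  nb <- matrix(rnbinom(500 * 6, mu = 100, size = 1 / 0.4), 500, 6)
  phi_hat <- estimate_common_dispersion(nb, group)
  expect_gte(phi_hat, 0.25)
  expect_lte(phi_hat, 0.6)

  # identical columns carry no overdispersion signal
  same <- cbind(pois[, 1], pois[, 1], pois[, 1], pois[, 1])
  expect_lt(estimate_common_dispersion(same, factor(c("a", "a", "b", "b"))),
            0.01)
  expect_error(estimate_common_dispersion(matrix(0L, 5, 6), group),
               "all-zero")
})

test_that("exact test is symmetric with p = 1 at the balanced mode", {
  expect_equal(exact_nb_test(50, 50, 3, 3, 0.1), 1)
  expect_equal(exact_nb_test(30, 70, 3, 3, 0.1),
               exact_nb_test(70, 30, 3, 3, 0.1))
  expect_error(exact_nb_test(10, 10, 3, 3, -1), "negative")
  expect_equal(exact_nb_test(0, 0, 3, 3, 0.1), 1)
})

test_that("the phi -> 0 limit reproduces the exact binomial doubling test", {
  # independent oracle: direct binomial enumeration over outcomes with
  # probability <= the observed one
  binom_two_sided <- function(a, t, p_success) {
    probs <- dbinom(0:t, t, p_success)
    obs <- probs[a + 1]
    sum(probs[probs <= obs * (1 + 1e-12)])
  }
  for (t in c(5, 17, 40, 50)) {
    for (a in unique(c(0, 1, t %/% 3, t %/% 2, t))) {
      want <- binom_two_sided(a, t, 0.5)
      expect_equal(exact_nb_test(a, t - a, 4, 4, 0), want, tolerance = 1e-12)
      expect_equal(exact_nb_test(a, t - a, 4, 4, 1e-9), want,
                   tolerance = 1e-4)
    }
  }
  # unequal group sizes shift the conditional null accordingly
  expect_equal(exact_nb_test(20, 40, 2, 4, 0), binom_two_sided(20, 60, 1 / 3),
               tolerance = 1e-12)
})

test_that("NB conditional probabilities are a proper distribution", {
  t <- 60
  phi <- 0.3
  m <- t / 8
  logp <- dnbinom(0:t, size = 4 / phi, mu = 4 * m, log = TRUE) +
    dnbinom(t:0, size = 4 / phi, mu = 4 * m, log = TRUE)
  p <- exp(logp - max(logp))
  expect_gt(sum(p), 0)  # normalizable; the test function normalizes exactly
  expect_equal(exact_nb_test(t %/% 2, t - t %/% 2, 4, 4, phi), 1)
})

test_that("p-value adjustment matches the hand-worked ladder", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "bh"), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.3, "bonferroni"), 0.3)
  expect_equal(adjust_pvalues(rep(0.3, 4), "bonferroni"), rep(1, 4))
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "outside")
})

make_null_counts <- function(n_genes, n_per_group, phi, seed) {
  set.seed(seed)
  mu <- rlnorm(n_genes, log(60), 0.8)
  counts <- matrix(rnbinom(n_genes * 2 * n_per_group, mu = mu,
                           size = if (phi > 0) 1 / phi else Inf),
                   n_genes, 2 * n_per_group,
                   dimnames = list(sprintf("tRNA-Ala-AGC-%d-1",
                                           seq_len(n_genes)),
                                   paste0("s", seq_len(2 * n_per_group))))
  counts
}

test_that("run_de emits coherent columns and the ordering invariants", {
  counts <- make_null_counts(120, 4, 0.2, 65)
  group <- factor(rep(c("ctl", "trt"), each = 4))
  de <- run_de(counts, group)
  expect_true(all(de$PValue >= 0 & de$PValue <= 1))
  expect_true(all(de$BH <= de$Bonferroni + 1e-12))
  expect_true(all(de$Bonferroni >= de$PValue - 1e-12))
  expect_true(all(de$BH >= de$PValue - 1e-12))
  expect_true(all(is.finite(de$log2FC)))
})

test_that("swapping group labels negates log2FC and keeps p-values", {
  counts <- make_null_counts(100, 3, 0.15, 66)
  g1 <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  g2 <- factor(rep(c("a", "b"), each = 3), levels = c("b", "a"))
  de1 <- run_de(counts, g1)
  de2 <- run_de(counts, g2)
  expect_equal(de1$log2FC, -de2$log2FC, tolerance = 1e-10)
  expect_equal(de1$PValue, de2$PValue, tolerance = 1e-10)
})

test_that("planted four-fold signals are detected with high power", {
  set.seed(67)
  n_genes <- 300
  mu <- rlnorm(n_genes, log(80), 0.6)
  fc <- rep(1, n_genes)
  planted <- seq_len(30)
  fc[planted] <- 4
  counts <- cbind(
    matrix(rnbinom(n_genes * 5, mu = mu, size = 1 / 0.15), n_genes, 5),
    matrix(rnbinom(n_genes * 5, mu = mu * fc, size = 1 / 0.15), n_genes, 5))
  dimnames(counts) <- list(sprintf("tRNA-Gly-GCC-%d-1", seq_len(n_genes)),
                           paste0("s", 1:10))
  de <- run_de(counts, factor(rep(c("ctl", "trt"), each = 5)))
  hit <- de$significant[planted]
  expect_gte(mean(hit), 0.8)
  expect_lt(median(de$BH[planted]), median(de$BH))
})
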
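# Two-group differential expression for tRNA count tables: CPM, prevalence
# filtering, TMM normalization (Robinson-Oshlack), a common-dispersion
# negative-binomial exact test on library-size-equalized pseudo-counts, and
# Bonferroni / Benjamini-Hochberg adjustment.

#' Counts per million
#'
#' @param counts integer matrix (entities x samples).
#' @param lib_sizes per-sample library sizes; defaults to raw column sums.
#'   Pass effective sizes (column sum x TMM factor) for normalized CPM.
#' @return numeric matrix of the same shape.
#' @export
cpm_matrix <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("zero or negative library size")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Prevalence filter on CPM
#'
#' Keeps an entity when its CPM is at least `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param counts integer matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction required fraction of samples (default 0.9).
#' @param lib_sizes optional library sizes for the CPM computation.
#' @return list with `kept` (filtered matrix) and `removed` (row names).
#' @export
filter_low_counts <- function(counts, min_cpm = 1, min_fraction = 0.9,
                              lib_sizes = colSums(counts)) {
  stopifnot(ncol(counts) >= 1)
  cpm <- cpm_matrix(counts, lib_sizes)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(cpm >= min_cpm) >= need
  list(kept = counts[keep, , drop = FALSE],
       removed = rownames(counts)[!keep])
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: against a reference sample (by default the one
#' whose upper-quartile CPM is closest to the mean upper quartile), M and A
#' values over genes expressed in both samples are trimmed (30% two-sided on
#' M, 5% on A) and the factor is `2^` the inverse-asymptotic-variance
#' weighted mean of the surviving M values. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts integer matrix, at least two samples (post-filter).
#' @param ref_sample optional reference column index or name.
#' @param logratio_trim two-sided trim fraction on M (default 0.3).
#' @param sum_trim two-sided trim fraction on A (default 0.05).
#' @return numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  if (is.null(ref_sample)) {
    uq <- vapply(seq_len(ncol(counts)), function(s) {
      stats::quantile(counts[, s], 0.75) / lib[s]
    }, 0)
    ref_sample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(counts))
  }
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref_sample) return(1)
    tmm_pair(counts[, s], counts[, ref_sample], lib[s], lib[ref_sample],
             logratio_trim, sum_trim)
  }, 0)
  if (anyNA(f)) {
    warning("sample(s) with no usable genes for TMM; factor set to 1")
    f[is.na(f)] <- 1
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(NA_real_)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  # asymptotic variance of M (delta method on binomial proportions)
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (!n) return(NA_real_)
  if (max(abs(m)) < 1e-10) return(1)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Estimate a common negative-binomial dispersion
#'
#' Counts are equalized to the geometric-mean effective library size
#' (pseudo-counts, rounded half-to-even), and a single dispersion phi is
#' chosen to maximize the conditional log-likelihood summed over genes and
#' groups (conditioning on each group's total), searched over
#' `[1e-6, 4]`.
#'
#' @param counts integer matrix (post-filter).
#' @param group two-level factor over the columns.
#' @param lib_sizes effective library sizes (default raw column sums).
#' @return estimated dispersion (>= 0).
#' @export
estimate_common_dispersion <- function(counts, group,
                                       lib_sizes = colSums(counts)) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2, length(group) == ncol(counts))
  if (all(counts == 0)) stop("all-zero count matrix")
  pseudo <- pseudo_counts(counts, lib_sizes)
  opt <- stats::optimize(function(phi) cond_log_lik(phi, pseudo, group),
                         interval = c(1e-6, 4), maximum = TRUE, tol = 1e-6)
  max(opt$maximum, 0)
}

# Scale columns to the geometric-mean library size; round half-to-even.
pseudo_counts <- function(counts, lib_sizes) {
  geo <- exp(mean(log(lib_sizes)))
  round(sweep(counts, 2L, geo / lib_sizes, "*"))
}

# Conditional log-likelihood of the within-group counts given group totals,
# equal library sizes, NB dispersion phi (size r = 1/phi).
cond_log_lik <- function(phi, pseudo, group) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(group)) {
    y <- pseudo[, group == g, drop = FALSE]
    n <- ncol(y)
    t <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) +
      sum(lgamma(n * r) - lgamma(t + n * r)) -
      nrow(y) * n * lgamma(r)
  }
  ll
}

#' Two-sided exact negative-binomial test on group sums
#'
#' Conditions on the total `sum_a + sum_b`; group sums are NB with sizes
#' `n_a / phi` and `n_b / phi` (binomial limit as phi -> 0). The two-sided
#' p-value sums the conditional probabilities of all outcomes no more likely
#' than the observed one.
#'
#' @param sum_a,sum_b group total counts (library-size-equalized).
#' @param n_a,n_b group sizes.
#' @param phi common dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
exact_nb_test <- function(sum_a, sum_b, n_a, n_b, phi) {
  if (phi < 0) stop("negative dispersion")
  t <- sum_a + sum_b
  if (t == 0) return(1)
  a <- 0:t
  if (phi < 1e-10) {
    logp <- stats::dbinom(a, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    m <- t / (n_a + n_b)
    logp <- stats::dnbinom(a, size = n_a / phi, mu = n_a * m, log = TRUE) +
      stats::dnbinom(t - a, size = n_b / phi, mu = n_b * m, log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[sum_a + 1L]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up; input order
#' preserved. BH is the package's FDR column.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Two-group differential expression (TMM + NB exact test)
#'
#' The full edgeR-style path: TMM effective library sizes, common
#' dispersion, per-gene exact test on pseudo-counts, smoothed log2 fold
#' change and average log2 CPM, and all adjusted p-value columns. The
#' second factor level is the test group; positive `log2FC` means higher in
#' the test group.
#'
#' @param counts filtered integer matrix (entities x samples).
#' @param group two-level factor over the columns (first level = control).
#' @param fc_threshold fold-change cutoff for the significance flag
#'   (default 1.5, applied as `|log2FC| > log2(1.5)`).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param adjust adjustment used for the flag: `"bh"` or `"bonferroni"`.
#' @param prior_count smoothing prior per sample on the CPM scale entry
#'   (default 0.125) so all-zero groups keep a finite fold change.
#' @return data.frame of class `de_table`: `name`, `log2FC`, `avgLog2CPM`,
#'   `PValue`, `Bonferroni`, `BH`, `significant`.
#' @export
run_de <- function(counts, group, fc_threshold = 1.5, alpha = 0.05,
                   adjust = c("bh", "bonferroni"), prior_count = 0.125) {
  adjust <- match.arg(adjust)
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2, length(group) == ncol(counts))
  ctrl <- levels(group)[1L]
  test <- levels(group)[2L]
  if (any(tapply(colSums(counts), group, sum) == 0)) {
    stop("a group has zero total counts")
  }
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  phi <- estimate_common_dispersion(counts, group, lib_sizes = eff)
  pseudo <- pseudo_counts(counts, eff)
  in_a <- group == ctrl
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  sum_a <- rowSums(pseudo[, in_a, drop = FALSE])
  sum_b <- rowSums(pseudo[, !in_a, drop = FALSE])
  p_raw <- vapply(seq_len(nrow(counts)), function(i) {
    exact_nb_test(sum_a[i], sum_b[i], n_a, n_b, phi)
  }, 0)
  cpm <- cpm_matrix(counts, eff)
  prior_cpm <- prior_count * 1e6 / mean(eff)
  mean_a <- rowMeans(cpm[, in_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, !in_a, drop = FALSE])
  log2_fc <- log2((mean_b + prior_cpm) / (mean_a + prior_cpm))
  avg_log2_cpm <- rowMeans(log2(cpm + prior_cpm))
  bonf <- adjust_pvalues(p_raw, "bonferroni")
  bh <- adjust_pvalues(p_raw, "bh")
  p_adj <- if (adjust == "bh") bh else bonf
  out <- data.frame(name = rownames(counts),
                    log2FC = log2_fc,
                    avgLog2CPM = avg_log2_cpm,
                    PValue = p_raw,
                    Bonferroni = bonf,
                    BH = bh,
                    significant = abs(log2_fc) > log2(fc_threshold) &
                      p_adj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- c(control = ctrl, test = test)
  attr(out, "dispersion") <- phi
  attr(out, "tmm_factors") <- f
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a DE table as tab-delimited text
#' @param de a `de_table`.
#' @param path output path.
#' @param level optional aggregation level recorded in a `level` column.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path, level = NULL) {
  df <- as.data.frame(de)
  if (!is.null(level)) df <- cbind(df[1L], level = level, df[-1L])
  write_tsv(df, path, header = provenance_header(
    list(dispersion = signif(attr(de, "dispersion"), 6))))
}
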
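# Plot-ready tables for the four result displays (MDS, volcano, anticodon
# bar, amino-acid pyramid) plus thin ggplot2 renderers. The data tables are
# the test surface; rendering only maps columns to aesthetics.

#' Classical MDS of samples on leading log-fold-change distances
#'
#' The distance between two samples is the root-mean-square of the `top_k`
#' largest absolute log2-CPM differences across genes (all genes when fewer),
#' the leading-logFC convention. Coordinates come from classical (Torgerson)
#' scaling of the distance matrix with a deterministic sign convention (first
#' nonzero loading of each axis positive).
#'
#' @param log_cpm numeric matrix of log2 CPM (genes x samples), >= 3 samples.
#' @param top_k number of top divergent genes per pair (default 500).
#' @return list of class `mds_result`: `coords` (samples x 2), `eig`
#'   (eigenvalues), `dist` (symmetric matrix, zero diagonal).
#' @export
mds_coordinates <- function(log_cpm, top_k = 500L) {
  n <- ncol(log_cpm)
  if (n < 3) stop("MDS needs at least 3 samples")
  D <- matrix(0, n, n, dimnames = list(colnames(log_cpm), colnames(log_cpm)))
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      d <- abs(log_cpm[, s] - log_cpm[, t])
      top <- sort(d, decreasing = TRUE)[seq_len(min(top_k, length(d)))]
      D[s, t] <- D[t, s] <- sqrt(mean(top^2))
    }
  }
  fit <- stats::cmdscale(stats::as.dist(D), k = 2, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < 2) {
    coords <- cbind(coords, matrix(0, n, 2 - ncol(coords)))
  }
  for (j in 1:2) {
    i <- which(abs(coords[, j]) > 1e-9)[1L]
    if (!is.na(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(colnames(log_cpm), c("dim1", "dim2"))
  structure(list(coords = coords, eig = fit$eig, dist = D),
            class = "mds_result")
}

#' Volcano plot data
#'
#' @param de a `de_table` at the individual level.
#' @param fc_threshold fold-change cutoff (default 1.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param adjust adjusted-p column used: `"bh"` or `"bonferroni"`.
#' @return data.frame: `name`, `log2FC`, `neg_log10_padj`, `status` in
#'   `{up, down, ns}`.
#' @export
volcano_data <- function(de, fc_threshold = 1.5, alpha = 0.05,
                         adjust = c("bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!nrow(de)) {
    return(data.frame(name = character(0), log2FC = numeric(0),
                      neg_log10_padj = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  padj <- if (adjust == "bh") de$BH else de$Bonferroni
  sig <- abs(de$log2FC) > log2(fc_threshold) & padj < alpha
  status <- ifelse(sig & de$log2FC > 0, "up",
                   ifelse(sig & de$log2FC < 0, "down", "ns"))
  data.frame(name = de$name, log2FC = de$log2FC,
             neg_log10_padj = -log10(pmax(padj, 1e-300)),
             status = status, stringsAsFactors = FALSE)
}

#' Anticodon bar-plot data (isodecoder-level results)
#'
#' Counts significantly up- and downregulated isodecoders per
#' (isotype, anticodon) family.
#'
#' @param de a `de_table` whose names parse at the isodecoder level.
#' @return data.frame: `isotype`, `anticodon`, `n_up`, `n_down` (families
#'   with at least one significant isodecoder).
#' @export
anticodon_bar_data <- function(de) {
  empty <- data.frame(isotype = character(0), anticodon = character(0),
                      n_up = integer(0), n_down = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(de)) return(empty)
  parsed <- parse_trna_name(de$name, "isodecoder")
  sig <- de$significant
  if (!any(sig)) return(empty)
  key <- paste(parsed$isotype, parsed$anticodon, sep = "-")[sig]
  up <- de$log2FC[sig] > 0
  n_up <- tapply(up, key, sum)
  n_down <- tapply(!up, key, sum)
  keys <- sort(names(n_up))
  data.frame(isotype = sub("-.*$", "", keys),
             anticodon = sub("^.*-", "", keys),
             n_up = as.integer(n_up[keys]),
             n_down = as.integer(n_down[keys]),
             stringsAsFactors = FALSE)
}

#' Amino-acid pyramid data (isoacceptor-level results)
#'
#' Counts significantly up- and downregulated isoacceptors per amino acid,
#' ordered by amino-acid code.
#'
#' @param de a `de_table` whose names parse at the isoacceptor level.
#' @return data.frame: `isotype`, `n_up`, `n_down`.
#' @export
aa_pyramid_data <- function(de) {
  empty <- data.frame(isotype = character(0), n_up = integer(0),
                      n_down = integer(0), stringsAsFactors = FALSE)
  if (!nrow(de)) return(empty)
  parsed <- parse_trna_name(de$name, "isoacceptor")
  sig <- de$significant
  if (!any(sig)) return(empty)
  key <- parsed$isotype[sig]
  up <- de$log2FC[sig] > 0
  n_up <- tapply(up, key, sum)
  n_down <- tapply(!up, key, sum)
  keys <- sort(names(n_up))
  data.frame(isotype = keys,
             n_up = as.integer(n_up[keys]),
             n_down = as.integer(n_down[keys]),
             stringsAsFactors = FALSE)
}

#' Render an MDS plot
#' @param mds an `mds_result`.
#' @param groups optional factor of sample groups for coloring.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_mds <- function(mds, groups = NULL, title = "MDS of samples") {
  df <- data.frame(sample = rownames(mds$coords), mds$coords,
                   stringsAsFactors = FALSE)
  df$group <- if (is.null(groups)) "all" else as.character(groups)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::labs(title = title, x = "Leading logFC dim 1",
                  y = "Leading logFC dim 2") +
    ggplot2::theme_bw()
}

#' Render a volcano plot
#' @param vd data from [volcano_data()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_volcano <- function(vd, title = "Differential tRNA expression") {
  ggplot2::ggplot(vd, ggplot2::aes(.data$log2FC, .data$neg_log10_padj,
                                   color = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(up = "red", down = "blue",
                                           ns = "grey60")) +
    ggplot2::labs(title = title, x = "log2 fold change",
                  y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' Render the anticodon bar plot
#' @param bd data from [anticodon_bar_data()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_anticodon_bar <- function(bd, title = "Significant isodecoders per anticodon") {
  long <- rbind(
    data.frame(family = paste(bd$isotype, bd$anticodon, sep = "-"),
               direction = "up", n = bd$n_up),
    data.frame(family = paste(bd$isotype, bd$anticodon, sep = "-"),
               direction = "down", n = bd$n_down))
  long <- long[long$n > 0, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(.data$family, .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "red", down = "blue")) +
    ggplot2::labs(title = title, x = NULL, y = "significant isodecoders") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Render the amino-acid pyramid plot
#' @param pd data from [aa_pyramid_data()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_aa_pyramid <- function(pd, title = "Significant isoacceptors per amino acid") {
  long <- rbind(
    data.frame(isotype = pd$isotype, direction = "up", n = pd$n_up),
    data.frame(isotype = pd$isotype, direction = "down", n = -pd$n_down))
  long <- long[long$n != 0, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(.data$isotype, .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(up = "red", down = "blue")) +
    ggplot2::labs(title = title, x = NULL, y = "significant isoacceptors") +
    ggplot2::theme_bw()
}
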
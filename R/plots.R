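#' Boxplots of per-set accumulation scores for two cohorts
#'
#' One boxplot pair per gene set: the member genes' accumulation scores
#' in each cohort (0 for unmutated members), the visual used to compare
#' pathway-level mutation accumulation between cohorts.
#'
#' @param set_scores Result of [score_gene_sets()].
#' @return A ggplot object.
#' @export
plot_set_scores <- function(set_scores) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(set_scores$per_gene,
                  ggplot2::aes(x = set, y = score, fill = cohort)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                          outlier.size = 0.6) +
    ggplot2::labs(x = "gene set", y = "gene accumulation score",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Gene-by-sample pathogenicity class matrix
#'
#' Tile rendering of the recurrence matrix: rows are genes, columns
#' samples, colours the pathogenicity classes (benign, VUS, and the
#' three pathogenic bins).
#'
#' @param rec Result of [recurrent_pathogenic_genes()].
#' @return A ggplot object.
#' @export
plot_class_matrix <- function(rec) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  m <- as.data.table(copy(rec$matrix))
  m[, klass := factor(klass, levels = PATHOGENICITY_CLASSES)]
  m[, gene_symbol := factor(gene_symbol, levels = rev(rec$genes$gene_symbol))]
  fills <- c(benign = "#4daf4a", VUS = "white",
             pathogenic_low = "#ff7f00", pathogenic_mid = "#e41a1c",
             pathogenic_high = "grey40")
  ggplot2::ggplot(m, ggplot2::aes(x = sample_id, y = gene_symbol,
                                  fill = klass)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = fills, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}
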
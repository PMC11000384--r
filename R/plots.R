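#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' Plot a burden scan
#'
#' Gene-level Manhattan-style plot of `-log10(p)` per (gene, trait) pair,
#' with the significance threshold drawn as a dashed line.
#'
#' @param object A `burden_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burden_scan <- function(object, ...) {
  dat <- object$results %>%
    filter(!is.na(.data$p_value)) %>%
    mutate(gene = factor(.data$gene, levels = sort(unique(.data$gene))))
  ggplot(dat, aes(x = .data$gene, y = -log10(.data$p_value),
                  colour = .data$trait)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$p_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  title = "Gene-level rare-variant burden scan") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot gene-carrier-frequency tiers by subpopulation
#'
#' Bar chart of the number of genes per screening-tier category in each
#' subpopulation.
#'
#' @param gcf Output of [gene_gcf()].
#' @return A ggplot.
#' @export
plot_gcf_tiers <- function(gcf) {
  dat <- gcf %>%
    filter(.data$tier != "below") %>%
    count(.data$subpopulation, .data$tier)
  ggplot(dat, aes(x = .data$subpopulation, y = .data$n, fill = .data$tier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Genes above carrier-frequency tiers") +
    ggplot2::theme_minimal()
}

#' Plot subpopulation carrier burden
#'
#' Carrier percentage per subpopulation with homozygote-enrichment folds as
#' labels.
#'
#' @param summary Output of [subpop_summary()].
#' @return A ggplot.
#' @export
plot_subpop_burden <- function(summary) {
  ggplot(summary, aes(x = stats::reorder(.data$subpopulation,
                                         -.data$pct_carriers),
                      y = .data$pct_carriers)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(aes(label = sprintf("hom fold %.1f",
                                           .data$fold_hom_vs_ref)),
                       vjust = -0.4, size = 3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "% carrying ≥ 1 P/LP allele",
                  title = "Carrier burden by subpopulation") +
    ggplot2::theme_minimal()
}
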
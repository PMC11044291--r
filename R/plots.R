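#' Heatmap of a replication matrix
#'
#' Tile plot of the directed replication ratios: the row set is the
#' denominator, so reading along a row shows how well that set is
#' replicated by each other set.
#'
#' @param object A `replication_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replication_matrix
#' @export
autoplot.replication_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$ratio)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$ratio), "", sprintf("%.2f", .data$ratio))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1), na.value = "grey95") +
    ggplot2::labs(x = "replicating set", y = "denominator set",
                  fill = "ratio") +
    ggplot2::theme_minimal()
}

#' Bar chart of MMRP pattern sizes
#'
#' One bar per disorder x pattern, coloured by whether the pattern
#' contains eQTL — an UpSet-style count view of the multi-QTL gene
#' partition.
#'
#' @param object An `mmrp_patterns` tibble from [enumerate_mmrp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mmrp_patterns
#' @export
autoplot.mmrp_patterns <- function(object, ...) {
  df <- object %>% mutate(label = paste(.data$disorder, .data$profile))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$n_genes), y = .data$n_genes,
    fill = .data$contains_eqtl)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b"),
                               labels = c(`TRUE` = "with eQTL",
                                          `FALSE` = "without eQTL")) +
    ggplot2::labs(x = NULL, y = "genes in pattern", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of xWAS association results
#'
#' Plots each feature's association strength (`-log10 p`) against its
#' z-statistic, faceted by tool, with the Bonferroni survivors
#' highlighted.
#'
#' @param object An `xwas_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot xwas_results
#' @export
autoplot.xwas_results <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_stat,
                                   y = -log10(.data$p_value),
                                   color = .data$passes_correction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::facet_wrap(~ .data$tool) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b",
                                           `FALSE` = "grey60"),
                                na.value = "grey60") +
    ggplot2::labs(x = "z statistic", y = expression(-log[10](p)),
                  color = "significant") +
    ggplot2::theme_minimal()
}
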
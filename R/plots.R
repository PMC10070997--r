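#' Minimum-fold-change volcano of a specificity screen
#'
#' Plots each gene's minimum log2 fold change over included healthy tissues
#' against its worst adjusted p (-log10), with the pass thresholds drawn as
#' dashed lines. Candidate genes are highlighted; non-passing and
#' non-protein-coding genes are grey.
#'
#' @param object A `taa_screen` from [screen_specificity()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taa_screen
#' @export
autoplot.taa_screen <- function(object, ...) {
  df <- object$specificity
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$min_log2_fold_change,
    y = -log10(pmax(.data$worst_adjusted_p, 1e-300)),
    colour = .data$passes
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(
      xintercept = log2(object$params$fc_threshold),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(object$params$alpha),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red3", `FALSE` = "grey65"),
      name = "candidate"
    ) +
    ggplot2::labs(
      x = "minimum log2 fold change (tumor / healthy tissue)",
      y = "-log10 worst adjusted p"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-tissue expression boxes with fold-change reference lines
#'
#' Draws the five-number summaries from [summarize_expression()] as boxplots
#' (one facet per gene), with the reference-group median and the
#' `fc_threshold`-times-lower line dashed in red.
#'
#' @param summary Tibble from [summarize_expression()].
#' @return A ggplot.
#' @export
plot_expression_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(
        ymin = .data$min, lower = .data$q1, middle = .data$median,
        upper = .data$q3, ymax = .data$max
      ),
      stat = "identity"
    ) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$ref_median),
      linetype = "dashed", colour = "red3"
    ) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$ref_lower),
      linetype = "dashed", colour = "red3"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log2 CPM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)
    )
}

#' Relative-expression bar plot
#'
#' @param rel Tibble from [relative_expression()].
#' @return A ggplot of percentage relative expression per sample and gene.
#' @export
plot_relative_expression <- function(rel) {
  ggplot2::ggplot(rel, ggplot2::aes(
    x = .data$sample_id, y = .data$relative_expression_percent
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(x = NULL, y = "relative expression (% of HKG reference)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)
    )
}
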
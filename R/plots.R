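## ggplot2 displays for the main result types.

#' Waterfall plot of the filtering-cascade ledger
#'
#' @param x A `coseg_cascade` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coseg_cascade
#' @export
autoplot.coseg_cascade <- function(x, ...) {
  led <- x$ledger
  led$stage <- factor(led$stage, levels = led$stage)
  ggplot2::ggplot(led, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3, size = 3) +
    ggplot2::labs(x = "filter stage", y = "variants surviving",
                  title = "Filtering cascade") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Burden-test overview plot
#'
#' Case carrier count against -log10 p under the chosen model, one point per
#' gene; genes below `alpha` are labelled.
#'
#' @param burden A `coseg_burden` tibble.
#' @param model `"dominant"` or `"recessive"`.
#' @param alpha Significance threshold for labelling (default 0.05).
#' @return A ggplot.
#' @export
plot_burden <- function(burden, model = c("dominant", "recessive"),
                        alpha = 0.05) {
  model <- match.arg(model)
  df <- tibble(
    gene = burden$gene,
    carriers = if (model == "dominant") burden$n_case_carriers_dom
               else burden$n_case_carriers_rec,
    p = if (model == "dominant") burden$p_dom else burden$p_rec,
    variant_count = burden$variant_count
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$carriers, y = -log10(.data$p),
                                   colour = .data$variant_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_text(
      data = df[df$p < alpha, , drop = FALSE],
      ggplot2::aes(label = .data$gene), vjust = -0.6, size = 2.7,
      show.legend = FALSE
    ) +
    ggplot2::labs(x = "case carriers", y = expression(-log[10](p)),
                  colour = "variants",
                  title = paste("Gene burden,", model, "model")) +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Terms with raw p below `alpha`, sized by overlap and coloured by source
#' database (mirroring the usual over-representation display).
#'
#' @param rows Enrichment tibble from [hypergeometric_enrichment()].
#' @param alpha Display threshold on the raw p-value (default 0.01).
#' @return A ggplot.
#' @export
plot_enrichment <- function(rows, alpha = 0.01) {
  df <- rows[rows$p_raw < alpha, , drop = FALSE]
  df$term_name <- factor(df$term_name, levels = rev(unique(df$term_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_raw), y = .data$term_name,
                                   size = .data$overlap_size,
                                   colour = .data$source_tag)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, size = "overlap",
                  colour = "source", title = "Term enrichment") +
    ggplot2::theme_minimal()
}
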
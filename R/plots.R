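#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Barcodes-per-fragment histogram for a dictionary
#'
#' @param object An `mpra_barcode_map`.
#' @param min_barcodes Filter threshold to mark (default 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_barcode_map
#' @export
autoplot.mpra_barcode_map <- function(object, min_barcodes = 12L, ...) {
  dist <- dplyr::count(object$entries, .data$fragment_id, name = "n_barcodes")
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$n_barcodes)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = min_barcodes - 0.5,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "barcodes per fragment", y = "fragments",
                  title = "Barcode dictionary coverage") +
    ggplot2::theme_minimal()
}

#' Volcano plot of allele-specific activity tests
#'
#' @param object An `mpra_diff` tibble from [test_fragments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_diff
#' @export
autoplot.mpra_diff <- function(object, ...) {
  tested <- tibble::as_tibble(object)[object$status == "ok", ]
  ggplot2::ggplot(tested,
                  ggplot2::aes(x = .data$effect,
                               y = -log10(.data$p_value),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "allelic effect (log2)", y = "-log10 p",
                  title = "Allele-specific reporter activity") +
    ggplot2::theme_minimal()
}

#' Pairwise r-squared heatmap
#'
#' @param ld Output of [ld_matrix()].
#' @return A ggplot object.
#' @export
plot_ld_heatmap <- function(ld) {
  both <- dplyr::bind_rows(
    ld,
    dplyr::rename(ld, variant_i = "variant_j", variant_j = "variant_i"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$variant_i, y = .data$variant_j,
                                     fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
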
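#' Violin/jitter plot of allelic ratios
#'
#' Informative features only; one panel position per chromosome class
#' (autosomal vs X) when the table carries `is_x_linked`.
#'
#' @param calls An `ase_calls` table.
#' @return A ggplot object.
#' @export
plot_allelic_ratio <- function(calls) {
  d <- dplyr::filter(tibble::as_tibble(calls), .data$informative)
  d$group <- if ("is_x_linked" %in% names(d)) {
    ifelse(d$is_x_linked, "X-linked", "autosomal")
  } else {
    "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_jitter(
      ggplot2::aes(colour = .data$category), width = 0.15, size = 0.8, alpha = 0.7
    ) +
    ggplot2::geom_hline(yintercept = c(0.3, 0.7), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "allelic ratio (maternal / tagged)",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Maternal/paternal read counts per isoform
#'
#' @param iso_counts Output of [count_isoform_alleles()].
#' @return A ggplot object.
#' @export
plot_isoform_counts <- function(iso_counts) {
  d <- iso_counts |>
    tidyr::pivot_longer(
      c("maternal", "paternal"), names_to = "allele", values_to = "reads"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transcript_id, y = .data$reads,
                                  fill = .data$allele)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(maternal = "#c0392b",
                                          paternal = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter plot of allelic ratios from two platforms
#'
#' @param object An `ase_concordance` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_concordance
#' @export
autoplot.ase_concordance <- function(object, ...) {
  d <- object$joined |>
    dplyr::mutate(agree = .data$category_a == .data$category_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio_a, y = .data$ratio_b,
                                  colour = .data$agree)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "allelic ratio (table A)", y = "allelic ratio (table B)",
                  colour = "category agrees") +
    ggplot2::theme_minimal()
}
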
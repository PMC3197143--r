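# ggplot2 views of the main result types.

#' MA plot of differential calls
#'
#' Log2 fold change against log10 of the summed count fractions, with
#' significant features and zero-in-one-condition features as their own
#' classes.
#'
#' @param ma Tibble from [ma_values()].
#' @param calls Optional `diff_calls` tibble supplying significance.
#' @return A ggplot object.
#' @export
plot_ma <- function(ma, calls = NULL) {
  d <- ma
  d$class <- ifelse(d$zero_flag, "zero in one condition", "tested")
  if (!is.null(calls)) {
    sig <- calls$feature_id[calls$significant]
    d$class[d$feature_id %in% sig] <- "significant"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$concentration + 1e-9),
                                  y = .data$m, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      tested = "grey40", significant = "red3",
      `zero in one condition` = "goldenrod")) +
    ggplot2::labs(x = "log10 concentration (summed count fractions)",
                  y = "M (log2 fold change, T/NT)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.diff_calls <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = log2((.data$mean_tumor + .data$mean_normal) / 2 + 1),
    y = .data$log2fc, colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red3",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "log2 mean expression", y = "log2 fold change",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Saturation curve plot
#'
#' @param curve Tibble from [saturation_curve()].
#' @param expected Optional tibble from [saturation_expected()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve, expected = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$bin,
                                           y = .data$genes_detected)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "raw reads sampled", y = "genes detected") +
    ggplot2::theme_minimal()
  if (!is.null(expected))
    p <- p + ggplot2::geom_line(
      data = expected,
      ggplot2::aes(x = .data$bin, y = .data$expected_detected),
      linetype = 2, colour = "blue")
  p
}

#' Sample-correlation heat map
#'
#' @param pcc Result of [sample_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_sample_correlation <- function(pcc) {
  m <- pcc$matrix
  d <- tibble(a = rep(rownames(m), times = ncol(m)),
              b = rep(colnames(m), each = nrow(m)),
              pcc = as.vector(m))
  ggplot2::ggplot(d, ggplot2::aes(.data$a, .data$b, fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-exon expression profile of one gene across conditions
#'
#' The per-condition mean normalized counts for each exon of a gene in
#' transcription order -- the coverage-curve view used to inspect
#' gene-versus-exon regulation patterns.
#'
#' @param exon_expression Tibble: exon id column then per-sample values.
#' @param design Design tibble.
#' @param annotation A `genome_annotation`.
#' @param gene Gene id.
#' @return A ggplot object.
#' @export
plot_exon_profile <- function(exon_expression, design, annotation, gene) {
  ord <- gene_exon_order(annotation, gene)
  id_col <- names(exon_expression)[1]
  d <- exon_expression |>
    filter(.data[[id_col]] %in% ord$exon_id) |>
    tidyr::pivot_longer(-dplyr::all_of(id_col), names_to = "sample_id") |>
    inner_join(design, by = "sample_id") |>
    group_by(.data[[id_col]], .data$condition) |>
    summarise(mean_value = mean(.data$value), .groups = "drop") |>
    mutate(rank = match(.data[[id_col]], ord$exon_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$mean_value,
                                  colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(tumor = "red3",
                                            normal = "blue3")) +
    ggplot2::labs(x = "exon (transcription order)",
                  y = "mean expression", colour = NULL, title = gene) +
    ggplot2::theme_minimal()
}
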
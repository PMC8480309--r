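#' Bar chart of up/down/notsig DE counts per consecutive contrast
#'
#' @param calls Tidied DE calls (e.g. `run$de` or `tidy()` of a
#'   [call_de()] result), with `layer`, `contrast_label`, `call`,
#'   `untested` columns.
#' @return A ggplot object.
#' @export
plot_de_counts <- function(calls) {
  counts <- calls |>
    filter(!.data$untested) |>
    count(.data$layer, .data$contrast_label, .data$call, name = "n_genes")
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$contrast_label, y = .data$n_genes, fill = .data$call
  )) +
    ggplot2::geom_col(position = "stack", colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = c(up = "#c0392b", down = "#27ae60", notsig = "white")
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$layer)) +
    ggplot2::labs(
      x = "consecutive time points (HAI)", y = "genes", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Per-gene correlation distributions across lags
#'
#' @param per_gene `per_gene` element of
#'   [delay_correlation_enhancement()].
#' @return A ggplot object (boxplots of rho per lag, faceted by layer
#'   pair).
#' @export
plot_lag_correlation <- function(per_gene) {
  ggplot2::ggplot(
    per_gene |> filter(!is.na(.data$rho)),
    ggplot2::aes(x = factor(.data$lag), y = .data$rho)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    ggplot2::facet_wrap(ggplot2::vars(.data$layer_pair)) +
    ggplot2::labs(x = "protein lag (contrasts)", y = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Aligned mean profiles of delayed-response genes
#'
#' Polysomal profiles on the real time axis; protein profiles shifted back
#' by their delay so that matched steps coincide.
#'
#' @param profiles Tibble from [shifted_profiles()].
#' @return A ggplot object.
#' @export
plot_shifted_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$aligned_index, y = .data$mean_value,
    colour = .data$layer, group = .data$layer
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$klass), ggplot2::vars(.data$shift),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "time index (protein shifted back by its delay)",
      y = "mean log2 abundance", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated DE fit
#'
#' @param object A `moderated_de` tibble (after [call_de()] for colouring).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.moderated_de <- function(object, ...) {
  d <- as_tibble(object) |> filter(!is.na(.data$p_raw))
  if (!"call" %in% names(d)) d$call <- "notsig"
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p_raw), colour = .data$call
  )) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#27ae60", notsig = "grey60")
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast_label)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 raw p") +
    ggplot2::theme_minimal()
}
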
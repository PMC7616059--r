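#' Plot a contact-probability scaling curve
#'
#' @param curve Tibble from [scaling_curve()].
#' @return A ggplot.
#' @export
plot_scaling_curve <- function(curve) {
  curve |>
    filter(count > 0) |>
    ggplot2::ggplot(ggplot2::aes(sep_mid, prob)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence separation (bp)", y = "contact probability") +
    ggplot2::theme_classic()
}

#' Plot separation-class fractions
#'
#' @param fractions Tibble from [separation_fractions()] (optionally
#'   with a `cell_id` column to facet boxplots by class).
#' @return A ggplot.
#' @export
plot_separation_fractions <- function(fractions) {
  p <- ggplot2::ggplot(fractions, ggplot2::aes(class, fraction))
  if ("cell_id" %in% names(fractions)) {
    p <- p + ggplot2::geom_boxplot()
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "fraction of contacts") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a saddle matrix
#'
#' @param sad Output of [saddle()].
#' @return A ggplot heatmap (group 1 = most B, highest group = most A).
#' @export
plot_saddle <- function(sad) {
  m <- sad$saddle
  df <- tidyr::crossing(row = seq_len(nrow(m)), col = seq_len(ncol(m))) |>
    mutate(value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(col, row, fill = log2(value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "compartment score group", y = "compartment score group",
                  fill = "log2 O/E") +
    ggplot2::theme_classic()
}

#' Plot scaled hub abundance across intermingling groups
#'
#' @param abundance Tibble from [hub_abundance_by_intermingling()].
#' @return A ggplot with bootstrap error bars.
#' @export
plot_hub_abundance <- function(abundance) {
  ggplot2::ggplot(abundance, ggplot2::aes(factor(group), scaled_abundance)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = scaled_abundance - boot_sd,
                                        ymax = scaled_abundance + boot_sd),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "intermingling group (low to high)",
                  y = "scaled hub abundance") +
    ggplot2::theme_classic()
}

#' Plot an enhancer-promoter enrichment heatmap
#'
#' @param enrichment Tibble from [shuffle_and_test()].
#' @return A ggplot tile heatmap of log2 fold change with significance
#'   stars (`*` q < 0.05, `**` q < 0.01, `***` q < 0.001).
#' @export
plot_enrichment_heatmap <- function(enrichment) {
  enrichment |>
    mutate(stars = dplyr::case_when(fdr_q < 0.001 ~ "***",
                                    fdr_q < 0.01 ~ "**",
                                    fdr_q < 0.05 ~ "*", TRUE ~ "")) |>
    ggplot2::ggplot(ggplot2::aes(site_class, anchor_category, fill = log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = stars)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "contact-site class", y = "anchor category",
                  fill = "log2 FC") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-class trans-density distributions
#'
#' @param density Output of [trans_density()].
#' @return A ggplot of scaled-density histograms per class.
#' @export
plot_trans_density <- function(density) {
  ggplot2::ggplot(density$by_class,
                  ggplot2::aes(scaled_density, fill = class)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "scaled trans density (background median = 1)",
                  y = "beads") +
    ggplot2::theme_classic()
}

#' Posterior densities of a Poisson-beta fit
#'
#' @param object A `pb_fit`.
#' @param ... Unused.
#' @return A ggplot of the marginal posteriors for `k_on`, `k_off`,
#'   `s` and the active fraction.
#' @export
autoplot.pb_fit <- function(object, ...) {
  if (isTRUE(object$excluded_low_expression)) {
    abort("Cannot plot an excluded fit.")
  }
  df <- tibble(
    parameter = rep(c("k_on", "k_off", "s", "active fraction"),
                    each = nrow(object$draws)),
    value = c(object$draws[, "k_on"], object$draws[, "k_off"],
              object$draws[, "s"], object$active_fraction_draws)
  )
  ggplot2::ggplot(df, ggplot2::aes(value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = object$gene) +
    ggplot2::theme_classic()
}
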
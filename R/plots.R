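#' Boxplot of pctMT by compartment and patient
#'
#' @param t A `cell_table` with a `pctmt` metadata column (see
#'   [add_pctmt()]).
#' @param threshold HighMT cutoff drawn as a dashed line (default 15).
#' @return A ggplot object.
#' @export
plot_pctmt_by_compartment <- function(t, threshold = 15) {
  ggplot2::ggplot(t$cell_meta,
                  ggplot2::aes(x = .data$patient_id, y = .data$pctmt,
                               fill = .data$compartment)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "patient", y = "pctMT (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Null distribution and observed MT residual of the bulk comparison
#'
#' @param object A `highmt_residual_test`.
#' @param ... Unused.
#' @return A ggplot object: the resampled null with its 95% band and the
#'   observed MT mean residual as a vertical line.
#' @export
autoplot.highmt_residual_test <- function(object, ...) {
  df <- tibble::tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::annotate("rect", xmin = object$null_ci95[1],
                      xmax = object$null_ci95[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_vline(xintercept = object$mt_mean_residual,
                        color = "firebrick") +
    ggplot2::labs(x = "mean residual of sampled genes",
                  y = "count",
                  subtitle = sprintf("MT mean residual %.3f, p = %.4g",
                                     object$mt_mean_residual, object$p_raw)) +
    ggplot2::theme_minimal()
}

#' Heatmap of pathway dysregulation deltas
#'
#' @param deltas Long tibble from [pathway_delta_matrix()].
#' @return A ggplot tile plot, pathways ordered by median delta.
#' @export
plot_pathway_deltas <- function(deltas) {
  ord <- deltas |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(med = stats::median(.data$delta, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$med)
  deltas$pathway <- factor(deltas$pathway, levels = ord$pathway)
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$study, y = .data$pathway,
                                       fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "median score\nHighMT - LowMT") +
    ggplot2::theme_minimal()
}

#' Per-drug median correlation ranking
#'
#' @param x A `highmt_drug_assoc` from [drug_association()].
#' @param ... Unused.
#' @return A ggplot object: drugs ordered by median pctMT-IC50 correlation,
#'   top/bottom tails highlighted.
#' @export
autoplot.highmt_drug_assoc <- function(x, ...) {
  med <- x$rankings$medians |>
    dplyr::mutate(tail = dplyr::case_when(
      .data$drug %in% x$rankings$top$drug ~ "resistance tail",
      .data$drug %in% x$rankings$bottom$drug ~ "sensitivity tail",
      TRUE ~ "middle"
    ))
  ggplot2::ggplot(med, ggplot2::aes(
    x = stats::reorder(.data$drug, .data$median_r),
    y = .data$median_r, fill = .data$tail)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median Pearson r (pctMT vs IC50)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Spatial patch map of malignant median pctMT
#'
#' @param patches Output of [patch_median_pctmt()].
#' @param show_excluded Draw excluded patches in grey (default TRUE).
#' @return A ggplot tile map of the patch grid.
#' @export
plot_spatial_patches <- function(patches, show_excluded = TRUE) {
  if (!show_excluded) patches <- patches[!patches$excluded, ]
  ggplot2::ggplot(patches, ggplot2::aes(
    xmin = .data$x_min, xmax = .data$x_max,
    ymin = .data$y_min, ymax = .data$y_max,
    fill = .data$median_pctmt)) +
    ggplot2::geom_rect(color = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  fill = "median pctMT\n(malignant)") +
    ggplot2::theme_minimal()
}
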
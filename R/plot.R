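# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of differential occupancy
#'
#' log2 fold change (mutant vs WT) against -log10 FDR, one point per
#' (peak, subunit), coloured by call.
#'
#' @param object A `"drm_diff"` from [test_occupancy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drm_diff <- function(object, ...) {
  df <- tidy(object) |>
    mutate(call = dplyr::case_when(
      .data$significant_decrease ~ "decreased",
      .data$significant_increase ~ "increased",
      TRUE ~ "unchanged"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$fdr), colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(decreased = "#2166ac",
                                            increased = "#b2182b",
                                            unchanged = "grey60")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$subunit)) +
    ggplot2::labs(x = "log2 fold change (mutant / WT)", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of annotation categories
#' @param annotations A `"drm_annotation"` tibble ([annotate_peaks()]).
#' @return A ggplot object.
#' @export
plot_annotation_categories <- function(annotations) {
  df <- as_tibble(annotations) |>
    dplyr::count(category = factor(.data$category, levels = ANNOTATION_CATEGORIES))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = "peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Distribution of per-peak subunit decreases by class
#' @param classes A `"drm_classes"` tibble ([classify_peaks()]).
#' @return A ggplot object.
#' @export
plot_peak_classes <- function(classes) {
  df <- as_tibble(classes) |>
    dplyr::count(.data$class_label, .data$n_subunits_decreased)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_subunits_decreased, .data$n,
                                   fill = .data$class_label)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(I = "#2166ac", II = "grey60"),
                               name = "class") +
    ggplot2::labs(x = "subunits with significant decrease", y = "peaks") +
    ggplot2::theme_minimal()
}
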
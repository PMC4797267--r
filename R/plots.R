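#' Volcano plot of a two-condition occupancy comparison
#'
#' Log2 fold change (treated over untreated) against -log10 p-value, one
#' point per evaluation site, colored by class.
#'
#' @param object An `occupancy_diff` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_diff <- function(object, ...) {
  p <- attr(object, "params")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold, y = .data$neglog10_p,
                                   color = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(p$fold_cut), log2(p$fold_cut)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p$p_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(induced = "#2166ac",
                                           repressed = "#1a9850",
                                           common = "#b2182b")) +
    ggplot2::labs(x = "log2 fold change (treated / untreated)",
                  y = "-log10 p-value", color = "class") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.occupancy_diff
#' @export
plot_volcano <- function(object, ...) autoplot.occupancy_diff(object, ...)

#' Bar chart of genomic category fractions per site class
#'
#' @param profile A [category_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_category_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$category,
                                        y = .data$fraction,
                                        fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of sites", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of motif-occurrence fractions per site class
#'
#' The dashed line marks the sampled genomic background rate.
#'
#' @param report A [motif_fraction_report()] tibble.
#' @return A ggplot object.
#' @export
plot_motif_fractions <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_hline(yintercept = report$background_fraction[1],
                        linetype = "dashed") +
    ggplot2::labs(x = "class", y = "motif-positive fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
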
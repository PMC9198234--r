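#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise method comparisons
#'
#' @param x A `biomech_comparison` from [build_tables()].
#' @param ... Unused.
#' @return A tibble with one row per (side, measure, method pair):
#'   t statistic, degrees of freedom, p-value, adjusted p and significance.
#' @export
tidy.biomech_comparison <- function(x, ...) {
  x$comparisons
}

#' One-row overview of a method comparison
#'
#' @param x A `biomech_comparison` from [build_tables()].
#' @param ... Unused.
#' @return A one-row tibble: cohort and comparison counts, test mode, alpha,
#'   and the number of significant comparisons.
#' @export
glance.biomech_comparison <- function(x, ...) {
  tibble::tibble(
    n_specimens = length(unique(x$summaries$specimen_id)),
    n_methods = length(x$methods),
    n_models = nrow(x$summaries),
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    mode = x$mode,
    alpha = x$alpha
  )
}

#' Plot group means across segmentation methods
#'
#' Line plot of the per-method group means of the four biomechanical
#' measures, one panel per measure, colored by side — the visual analog of
#' the overall results table.
#'
#' @param object A `biomech_comparison` from [build_tables()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biomech_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$means,
    ggplot2::aes(x = .data$method, y = .data$mean,
                 group = .data$side, colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "segmentation method", y = "group mean",
                  colour = "side") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of comparison p-values
#'
#' Tile plot of p-values for each (measure, method pair) per side, with
#' significant cells outlined.
#'
#' @param x A `biomech_comparison` from [build_tables()].
#' @return A ggplot object.
#' @export
plot_comparison_pvalues <- function(x) {
  stopifnot(inherits(x, "biomech_comparison"))
  ggplot2::ggplot(
    x$comparisons,
    ggplot2::aes(x = .data$method_b, y = .data$measure,
                 fill = .data$p_value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.4f%s", .data$p_value,
                      ifelse(.data$significant, " *", ""))), size = 3) +
    ggplot2::facet_wrap(~side) +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#ffffbf",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = paste("compared against", x$methods[1]), y = NULL,
                  fill = "p") +
    ggplot2::theme_minimal()
}
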
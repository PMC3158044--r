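#' Plot a duplex-formation dose-response curve
#'
#' Percent duplex against relative Hfq on a log axis, one line per focal
#' pair, with the 10% threshold that defines the lower and upper bounds
#' drawn as a horizontal reference.
#'
#' @param object An `hfq_sweep` from [hfq_sweep()].
#' @param threshold Reference threshold in percent (default 10; `NULL`
#'   omits it).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hfq_sweep
#' @export
autoplot.hfq_sweep <- function(object, threshold = 10, ...) {
  df <- dplyr::filter(object, is.finite(.data$relative_hfq),
                      is.finite(.data$percent_duplex))
  df$pair <- paste0("(", df$pair_i, ",", df$pair_j, ")")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$relative_hfq,
                                        .data$percent_duplex,
                                        colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative Hfq (total Hfq / total focal mRNA)",
                  y = "% target mRNA in duplex", colour = "pair") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "grey40")
  if (length(unique(df$pair)) == 1L)
    p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot Hfq allocation across a titration
#'
#' Stacked-area view of the fraction of Hfq held as free hexamer,
#' singly-bound complexes and cognate/non-cognate ternary complexes.
#'
#' @param sweep An `hfq_sweep`.
#' @return A ggplot object.
#' @export
plot_hfq_allocation <- function(sweep) {
  df <- dplyr::filter(sweep, .data$pair_i == .data$pair_i[1],
                      .data$pair_j == .data$pair_j[1])
  long <- tidyr::pivot_longer(
    df, c("free", "srna_bound", "mrna_bound", "cognate_ternary",
          "noncognate_ternary"),
    names_to = "form", values_to = "fraction")
  long$form <- factor(long$form,
                      c("free", "srna_bound", "mrna_bound",
                        "cognate_ternary", "noncognate_ternary"))
  ggplot2::ggplot(long, ggplot2::aes(.data$relative_hfq, .data$fraction,
                                     fill = .data$form)) +
    ggplot2::geom_area() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative Hfq", y = "fraction of total Hfq",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot robustness summaries across a scanned variable
#'
#' Lower bound, upper bound, robustness and maximum percent duplex as
#' small multiples against a user-chosen x variable (e.g. network size),
#' one line per topology/label group.
#'
#' @param summaries A tibble of [bounds_and_robustness()] rows carrying
#'   the columns named by `x` and `group`.
#' @param x Name of the x-axis column.
#' @param group Optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_robustness <- function(summaries, x, group = NULL) {
  long <- tidyr::pivot_longer(
    summaries, c("lower_bound", "upper_bound", "robustness",
                 "max_percent_duplex"),
    names_to = "metric", values_to = "value")
  aes <- if (is.null(group))
    ggplot2::aes(.data[[x]], .data$value)
  else
    ggplot2::aes(.data[[x]], .data$value, colour = .data[[group]])
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
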
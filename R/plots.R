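# Plotting and tidier methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' Box plot of integration-age estimates by category
#'
#' The classic diffusion-summary view: one box per ortholog category,
#' whiskers at the observed range.
#'
#' @param estimates A tibble with columns `category` and `T` (Myr), e.g. the
#'   `ages.tsv` output of [run_all()].
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(estimates) {
  stopifnot(all(c("category", "T") %in% names(estimates)))
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$category, y = .data$T,
                               fill = .data$category)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "estimated integration time (Myr)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_age_distribution
#' @param object An `erv_age_summary`-like tibble (from [summarize_ages()]).
#' @param ... Unused.
#' @export
autoplot.erv_segmentation <- function(object, ...) {
  segs <- object$segments
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$parent, yend = .data$parent,
                   colour = .data$parent),
      linewidth = 4, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$breakpoints$position,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "query position (nt)", y = "assigned parent",
                  title = sprintf("two-parent segmentation (cost %.0f, sigma %.1f)",
                                  object$cost, object$sigma)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
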
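#' Forest-style plot of a disproportionality screen
#'
#' Reporting odds ratios with 95% confidence intervals on a log axis, one
#' row per term, signals highlighted.
#'
#' @param object A `signal_screen` from [screen_signals()].
#' @param top Plot at most this many terms by observed count (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_screen
#' @export
autoplot.signal_screen <- function(object, top = 30, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::slice_max(.data$a, n = top, with_ties = FALSE) |>
    dplyr::mutate(term = stats::reorder(.data$term, .data$ror))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ror, y = .data$term,
                                  colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ror_lo95,
                                          xmax = .data$ror_hi95)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey40"),
                                 name = "joint signal") +
    ggplot2::labs(x = "reporting odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a time-to-onset summary
#'
#' Monthly-bin histogram of onset times (percent of cases per 30-day bin)
#' for one group of a [summarize_tto()] result.
#'
#' @param object A `tto_summary`.
#' @param group Which group to plot (default `"all"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tto_summary
#' @export
autoplot.tto_summary <- function(object, group = "all", ...) {
  d <- dplyr::filter(object$bins, .data$group == !!group)
  d$bin <- factor(d$bin, levels = d$bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "time to onset", y = "% of cases") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cumulative onset curve
#'
#' Cumulative proportion of cases with onset at or before each day, per
#' group.
#'
#' @param summary A `tto_summary` from [summarize_tto()].
#' @param groups Optional character vector of groups to show (default all).
#' @return A ggplot object.
#' @export
plot_tto_cumulative <- function(summary, groups = NULL) {
  d <- summary$cumulative
  if (!is.null(groups)) d <- dplyr::filter(d, .data$group %in% groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$days, y = .data$cum_prop,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time to onset (days)", y = "cumulative proportion") +
    ggplot2::theme_minimal()
}
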
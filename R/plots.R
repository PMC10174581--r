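#' Plot a secondary-extinction curve
#'
#' Cumulative proportion of extinct species against the proportion of primary
#' removals, with the 1:1 line of a cascade-free web for reference; the area
#' between the two is the SEA.
#'
#' @param object an [extinction_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.extinction_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prop_primary,
                                   y = .data$prop_extinct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "proportion of primary extinctions",
      y = "proportion of cumulative extinctions",
      title = sprintf("%s removal, t = %g (SEA = %.3f, R50 = %.3f)",
                      object$method, object$threshold, sea(object),
                      r50(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-method comparison summaries
#'
#' Mean SEA and R50 per removal strategy with error bars (standard error of
#' the mean across webs).
#'
#' @param object a [run_comparison()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.web_comparison <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$method, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "removal strategy", y = "mean ± SEM") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Mean R50 (or SEA) against the extinction threshold, one line per strategy.
#'
#' @param sweep a tibble from [threshold_sweep()] (rows from several methods
#'   can be bound together).
#' @param metric `"r50"` or `"sea"`.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep, metric = c("r50", "sea")) {
  metric <- match.arg(metric)
  df <- sweep |>
    group_by(.data$method, .data$t) |>
    summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "extinction threshold t", y = toupper(metric),
                  colour = "strategy") +
    ggplot2::theme_minimal()
}
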
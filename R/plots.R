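# Plots: the outcome's semicontinuous shape and coefficient summaries.

#' Histogram of weekly activity minutes with the zero spike highlighted
#'
#' The semicontinuous outcome has a point mass at exactly zero (no activity)
#' and a right-skewed positive part; this plot shows both, colouring the
#' zeros separately so the hurdle is visible.
#'
#' @param data Data frame with a `weekly_minutes` column.
#' @param binwidth Histogram bin width in minutes (default 30).
#' @return A ggplot object.
#' @export
plot_activity_histogram <- function(data, binwidth = 30) {
  stopifnot("weekly_minutes" %in% names(data))
  df <- tibble::tibble(
    weekly_minutes = data$weekly_minutes,
    status = factor(
      ifelse(data$weekly_minutes == 0, "no activity (exact zero)", "active"),
      levels = c("no activity (exact zero)", "active")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weekly_minutes, fill = .data$status)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c("firebrick", "steelblue")) +
    ggplot2::labs(
      x = "Leisure-time physical activity (minutes/week)",
      y = "Participants", fill = NULL,
      title = "Distribution of weekly activity minutes",
      subtitle = "Point mass at zero plus a right-skewed positive part"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ziglm_zig <- function(object, conf.level = 0.95, ...) {
  df <- tidy(object, conf.level = conf.level)
  df <- df[df$term != "intercept", , drop = FALSE]
  df$component <- factor(df$component,
    levels = c("logistic", "gamma"),
    labels = c("Zero process (log odds ratio)", "Duration (minutes/week)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_x") +
    ggplot2::labs(
      x = "Estimate (95% Wald interval)", y = NULL,
      title = "Two-part zero-inflated gamma model coefficients"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ziglm_recovery <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bias, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$bias - 2 * .data$empirical_se / sqrt(object$replicates),
      xmax = .data$bias + 2 * .data$empirical_se / sqrt(object$replicates)
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_x") +
    ggplot2::labs(
      x = "Bias (with 2 Monte-Carlo SEs)", y = NULL,
      title = "Parameter recovery across replicates"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
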
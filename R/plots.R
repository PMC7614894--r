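#' Plot a retention profile
#'
#' @param x A `retention_profile` tibble or `ratio_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_retention_profile <- function(x, ...) {
  if (inherits(x, "ratio_fit")) {
    pred <- predict_retention(x, rows = sort(unique(x$counts$start_row)))
    obs <- x$counts %>%
      mutate(observed = .data$n_retained / .data$n_clones,
             observed_norm = .data$observed / .data$observed[.data$start_row == 0])
    return(
      ggplot2::ggplot(pred, ggplot2::aes(x = .data$row, y = .data$probability)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             alpha = 0.25, fill = "steelblue") +
        ggplot2::geom_line(colour = "steelblue") +
        ggplot2::geom_point(data = obs, ggplot2::aes(x = .data$start_row, y = .data$observed_norm)) +
        ggplot2::labs(x = "starting row", y = "normalised retention probability",
                      title = sprintf("k_r/k_d = %.2f (95%% CI %.2f-%.2f)",
                                      x$ratio, x$ci_low, x$ci_high)) +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$row, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") + ggplot2::geom_point() +
    ggplot2::labs(x = "row", y = "normalised retention probability") +
    ggplot2::theme_minimal()
}

#' @rdname plot_retention_profile
#' @param object A `ratio_fit` or `retention_profile`.
#' @export
autoplot.ratio_fit <- function(object, ...) plot_retention_profile(object, ...)

#' @rdname plot_retention_profile
#' @export
autoplot.retention_profile <- function(object, ...) plot_retention_profile(object, ...)

#' Plot monoclonal drift
#'
#' @param x A `monoclonality_series` tibble (possibly several conditions).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_monoclonality <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$time_days / 7, y = .data$fraction_monoclonal,
                                  colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "weeks after labelling", y = "fraction of monoclonal crypts") +
    ggplot2::theme_minimal()
}

#' @rdname plot_monoclonality
#' @param object A `monoclonality_series`.
#' @export
autoplot.monoclonality_series <- function(object, ...) plot_monoclonality(object, ...)

#' Plot ablation recovery
#'
#' @param x An `ablation_trajectory` (or several summaries bound together).
#' @param ... Unused.
#' @return A ggplot of the mean lowest occupied row over time.
#' @export
plot_ablation_recovery <- function(x, ...) {
  summ <- if (inherits(x, "ablation_trajectory")) x$summary else x
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_days, y = .data$mean_lowest_row,
                                     colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "days after ablation", y = "mean lowest occupied row") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ablation_recovery
#' @param object An `ablation_trajectory`.
#' @export
autoplot.ablation_trajectory <- function(object, ...) plot_ablation_recovery(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
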
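#' Plot an MPC as a share bar chart
#'
#' @param object An [mpc()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' autoplot(aws_spectrum())
#' @export
autoplot.mpc <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$share,
                                   fill = .data$gene)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of the mutation pie chart") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of completion experiment results
#'
#' @param draws Integer completion counts from [simulate_completion()] (or
#'   the `"draws"` attribute of [completion_distribution()]).
#' @return A ggplot object with the mean, median and central-95% interval
#'   marked.
#' @examples
#' set.seed(1)
#' plot_completion(simulate_completion(rep(1, 16), reps = 2000))
#' @export
plot_completion <- function(draws) {
  qs <- q95(draws)
  df <- tibble(draws = draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draws)) +
    ggplot2::annotate("rect", xmin = qs[1], xmax = qs[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = mean(draws), colour = "red") +
    ggplot2::geom_vline(xintercept = median(draws), colour = "magenta",
                        linetype = "dashed") +
    ggplot2::labs(x = "observations until completion", y = "experiments") +
    ggplot2::theme_minimal()
}

#' Plot unevenness-estimation convergence
#'
#' @param object An `"estimation_error"` tibble from
#'   [estimation_error_experiment()].
#' @param ... Ignored.
#' @return A ggplot object: mean/median signed error with the central-95%
#'   band against the observation span.
#' @export
autoplot.estimation_error <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$obs)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         fill = "orange", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_error), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_error),
                       colour = "magenta", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "observation span (mutants sequenced)",
                  y = "signed unevenness error") +
    ggplot2::theme_minimal()
}

#' Plot the calibration quantile curves
#'
#' @param object An `"mpc_calibration"` from [calibrate_sigma()].
#' @param ... Ignored.
#' @return A ggplot object: simulated central-95% unevenness band across
#'   the sigma grid, the observed unevenness, the ML sigma and its CI.
#' @export
autoplot.mpc_calibration <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$sigma)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2_5, ymax = .data$q97_5),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_hline(yintercept = object$u_obs, colour = "grey30") +
    ggplot2::annotate("point", x = object$sigma_ml, y = object$u_obs,
                      shape = 8, size = 3) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = expression(sigma), y = "unevenness U") +
    ggplot2::theme_minimal()
}

#' Plot a standardized TMR distribution against the normal limit
#'
#' @param object A `"tmr_summary"` from [tmr_distribution()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tmr_summary <- function(object, ...) {
  df <- tibble(z = object$standardized)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 80, fill = "steelblue") +
    ggplot2::stat_function(fun = dnorm, colour = "red") +
    ggplot2::labs(x = "standardized total mutation rate", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a repeatability threshold curve
#'
#' @param object A `"repeatability_curve"` from [repeatability_curve()].
#' @param ... Ignored.
#' @return A ggplot object of the threshold ratio against sigma.
#' @export
autoplot.repeatability_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sigma, y = .data$r_thresh_mean)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$r_thresh_median),
                       colour = "white", linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(y = .data$r_thresh)) +
    ggplot2::labs(x = expression(sigma),
                  y = expression(r[thresh] ~ "(95% certainty)")) +
    ggplot2::theme_minimal()
}
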
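#' Plot a spectral parameterization fit
#'
#' Input spectrum, full model and aperiodic component on the fitted grid.
#'
#' @param object A `specparam_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.specparam_fit <- function(object, ...) {
  df <- tibble::tibble(
    frequency = rep(object$frequencies, 3),
    log_power = c(object$spectrum, object$model, object$aperiodic_curve),
    component = rep(c("spectrum", "model", "aperiodic"),
                    each = length(object$frequencies))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$log_power,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power",
                  title = sprintf("exponent %.2f, %d peak(s), R² = %.3f",
                                  object$aperiodic$exponent,
                                  nrow(object$peaks), object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot mediation effect estimates
#'
#' Point estimates with percentile confidence intervals for ACME, ADE and
#' the total effect.
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mediation_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "prop_mediated", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::labs(x = "Standardized effect", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot baseline-correction scenario curves
#'
#' Raw or corrected scenario trajectories; with corrected curves from
#' [apply_scheme()] the conflation (per-repetition) or disambiguation
#' (per-subject) is directly visible.
#'
#' @param trajectories Output of [build_scenarios()] or [apply_scheme()].
#' @return A ggplot.
#' @export
plot_scenarios <- function(trajectories) {
  ycol <- if ("corrected" %in% names(trajectories)) "corrected" else "power"
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(.data$time, .data[[ycol]],
                               color = .data$scenario,
                               linetype = factor(.data$repetition))) +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Power (a.u.)",
                  linetype = "Repetition") +
    ggplot2::theme_minimal()
}

#' Plot a time-frequency plane
#'
#' Channel-averaged log-power (optionally baseline-corrected per frequency
#' bin) for one repetition row of a spectral tensor.
#'
#' @param tensor A `spectral_tensor`.
#' @param row Repetition row index.
#' @param baseline Optional baseline window in ms; when given, the mean
#'   log-power of that window is subtracted per frequency bin.
#' @return A ggplot.
#' @export
plot_tfr <- function(tensor, row = 1, baseline = NULL) {
  plane <- apply(tensor$log_power[row, , , , drop = FALSE], c(3, 4), mean)
  if (!is.null(baseline)) {
    ti <- tensor$times >= baseline[1] & tensor$times <= baseline[2]
    plane <- plane - rowMeans(plane[, ti, drop = FALSE])
  }
  df <- tidyr::expand_grid(frequency = tensor$frequencies,
                           time = tensor$times)
  df$value <- as.vector(t(plane))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)",
                  fill = if (is.null(baseline)) "log10 power" else
                    "Δ log10 power") +
    ggplot2::theme_minimal()
}
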
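#' Plot a parameterized spectrum
#'
#' Shows the input log10 spectrum, the fitted aperiodic line and the full
#' model (aperiodic + peaks).
#'
#' @param object a `parameterized_spectrum`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot parameterized_spectrum
#' @export
autoplot.parameterized_spectrum <- function(object, ...) {
  ap_curve <- object$aperiodic$offset -
    object$aperiodic$exponent * log10(object$freq_hz)
  df <- tibble(
    freq_hz = rep(object$freq_hz, 3),
    value = c(object$log_power, ap_curve, object$model_log10),
    curve = rep(c("observed", "aperiodic", "model"),
                each = length(object$freq_hz))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                   colour = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power (uV²/Hz)",
                  title = sprintf("Aperiodic offset %.2f, exponent %.2f, R² %.3f",
                                  object$aperiodic$offset,
                                  object$aperiodic$exponent,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster permutation result
#'
#' The per-bin t curve with the cluster-forming threshold and shaded
#' significant clusters (cluster p < 0.05).
#'
#' @param object a `cluster_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$t_curve,
                       ggplot2::aes(x = .data$freq_hz, y = .data$t_stat)) +
    ggplot2::geom_hline(yintercept = c(-object$t_crit, object$t_crit),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "t statistic",
                  title = sprintf("%s vs %s (%d permutations)",
                                  object$groups[1], object$groups[2],
                                  object$n_perm)) +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$p_value < 0.05, , drop = FALSE]
  if (nrow(sig) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$freq_lo, xmax = .data$freq_hi,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "firebrick")
  }
  p
}

#' Plot group-mean spectra
#'
#' Group-averaged curves (log10 power for linear input) by ROI.
#'
#' @param curves long tibble with `group`, `roi` (optional), `freq_hz` and
#'   a value column.
#' @param value name of the value column.
#' @param log10_transform take log10 of the value (for linear power input).
#' @return A ggplot object.
#' @export
plot_group_spectra <- function(curves, value = "power_uv2_per_hz",
                               log10_transform = TRUE) {
  assert_cols(curves, c("group", "freq_hz", value), "`curves`")
  has_roi <- "roi" %in% names(curves)
  grp <- c("group", if (has_roi) "roi", "freq_hz")
  df <- curves %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(value = mean(.data[[value]]), .groups = "drop")
  if (log10_transform) df$value <- log10(df$value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = if (log10_transform) "log10 power (uV²/Hz)" else value) +
    ggplot2::theme_minimal()
  if (has_roi) p <- p + ggplot2::facet_wrap(~roi)
  p
}
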
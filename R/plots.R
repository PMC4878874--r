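#' Box-whisker plot of normalized FRET efficiencies
#'
#' Draws the two normalized distributions (donor+acceptor vs donor-only) with
#' the 1.5 x IQR whisker convention: boxes span the quartiles, whiskers the
#' extreme values inside the fences, and points outside them are drawn (or
#' hidden) as outliers.
#'
#' @param object A `fret_pair_result`.
#' @param show_outliers Draw outlier points (`TRUE`, default) or hide them.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fret_pair_result
#' @export
autoplot.fret_pair_result <- function(object, show_outliers = TRUE, ...) {
  df <- dplyr::bind_rows(
    tibble(group = "DA", efficiency = object$efficiencies_DA_pct),
    tibble(group = "D", efficiency = object$efficiencies_D_pct)
  )
  df$group <- factor(df$group, levels = c("DA", "D"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$efficiency)) +
    ggplot2::geom_boxplot(
      coef = 1.5,
      outlier.shape = if (show_outliers) 1 else NA,
      width = 0.5
    ) +
    ggplot2::labs(
      x = NULL, y = "FRET efficiency (%)",
      title = object$pair_name,
      subtitle = sprintf("p = %.3g (two-tailed Student t-test) - %s",
                         object$p_value,
                         if (isTRUE(object$positive)) "positive" else "negative")
    ) +
    ggplot2::theme_classic()
}

#' Plot a FRAP trace with its fitted exponential recovery
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity",
                  subtitle = if (isTRUE(object$converged)) {
                    sprintf("t-half = %.3g s, mobile fraction = %.2f, R² = %.3f",
                            object$t_half_s, object$mobile_fraction,
                            object$r_squared)
                  } else "fit did not converge") +
    ggplot2::theme_classic()
  if (!is.null(object$fitted_curve)) {
    p <- p + ggplot2::geom_line(
      data = object$fitted_curve,
      ggplot2::aes(x = .data$time_s, y = .data$fitted),
      linewidth = 0.8
    )
  }
  p
}

#' Plot an average FRAP recovery curve with a standard-deviation ribbon
#'
#' @param curve Output of [average_recovery_curve()].
#' @return A ggplot object.
#' @export
plot_recovery_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$intensity - .data$sd_intensity,
      ymax = .data$intensity + .data$sd_intensity
    ), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity") +
    ggplot2::theme_classic()
}

#' Plot spindle-length traces with scored anaphase events
#'
#' @param traces Long tibble with `cell_id`, `time_min`, `length_um`.
#' @param scores Optional output of [score_spindle_traces()]; onset and
#'   breakdown times are marked when supplied.
#' @return A ggplot object.
#' @export
plot_spindle_traces <- function(traces, scores = NULL) {
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_min,
                                            y = .data$length_um,
                                            group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = "spindle length (µm)") +
    ggplot2::theme_classic()
  if (!is.null(scores)) {
    marks <- tidyr::pivot_longer(
      scores[, c("cell_id", "onset_min", "breakdown_min")],
      cols = c("onset_min", "breakdown_min"),
      names_to = "event", values_to = "time_min"
    )
    marks <- dplyr::filter(marks, !is.na(.data$time_min))
    lengths_at <- dplyr::inner_join(
      traces, marks[, c("cell_id", "event", "time_min")],
      by = c("cell_id", "time_min")
    )
    p <- p + ggplot2::geom_point(
      data = lengths_at,
      ggplot2::aes(color = .data$event), size = 1.6
    )
  }
  p
}
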
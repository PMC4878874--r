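#' Tidy a FRET pair result
#'
#' One row per sample class (DA, D) with the normalized-efficiency
#' box-whisker statistics.
#'
#' @param x A `fret_pair_result`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `n`, `mean`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n_outliers`.
#' @method tidy fret_pair_result
#' @export
tidy.fret_pair_result <- function(x, ...) {
  row_for <- function(group, values) {
    bw <- if (length(values) >= 4) box_whisker_summary(values) else
      tibble(median = median(values), q1 = NA_real_, q3 = NA_real_,
             whisker_low = NA_real_, whisker_high = NA_real_,
             n_outliers = NA_integer_)
    tibble(
      group = group, n = length(values), mean = mean(values),
      median = bw$median, q1 = bw$q1, q3 = bw$q3,
      whisker_low = bw$whisker_low, whisker_high = bw$whisker_high,
      n_outliers = bw$n_outliers
    )
  }
  dplyr::bind_rows(
    row_for("DA", x$efficiencies_DA_pct),
    row_for("D", x$efficiencies_D_pct)
  )
}

#' Glance at a FRET pair result
#'
#' @param x A `fret_pair_result`.
#' @param ... Unused.
#' @return A one-row tibble: `pair_name`, `n_DA`, `n_D`, `mean_DA_pct`,
#'   `mean_D_pct`, `E_D_median`, `p_value`, `alpha`, `positive`.
#' @method glance fret_pair_result
#' @export
glance.fret_pair_result <- function(x, ...) {
  tibble(
    pair_name = x$pair_name,
    n_DA = x$n_DA,
    n_D = x$n_D,
    mean_DA_pct = mean(x$efficiencies_DA_pct),
    mean_D_pct = mean(x$efficiencies_D_pct),
    E_D_median = x$E_D_median,
    p_value = x$p_value,
    alpha = x$alpha,
    positive = x$positive
  )
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`term`, `estimate`).
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("k_per_s", "t_half_s", "plateau_fraction",
             "bleach_depth_fraction", "mobile_fraction"),
    estimate = c(x$k_per_s, x$t_half_s, x$plateau_fraction,
                 x$bleach_depth_fraction, x$mobile_fraction)
  )
}

#' Glance at a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k_per_s`, `t_half_s`, `mobile_fraction`,
#'   `r_squared`, `converged`, `n_post`.
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    k_per_s = x$k_per_s,
    t_half_s = x$t_half_s,
    mobile_fraction = x$mobile_fraction,
    r_squared = x$r_squared,
    converged = x$converged,
    n_post = x$n_post
  )
}
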
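#' Box-whisker summary with the 1.5 x IQR outlier rule
#'
#' Quartiles use inclusive linear interpolation (`stats::quantile()` type 7,
#' the common spreadsheet/plotting convention). Fences sit at
#' `q1 - 1.5 IQR` and `q3 + 1.5 IQR`; whiskers are the extreme *data* values
#' inside the fences, and every point outside them is an outlier.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return A tibble with one row: `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, and `outliers` (list-column).
#' @export
#' @examples
#' box_whisker_summary(c(1:9, 100))
box_whisker_summary <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric.")
  }
  if (length(values) < 4) {
    abort("box-whisker summary needs at least 4 values.")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  fence_low <- q[1] - 1.5 * iqr
  fence_high <- q[3] + 1.5 * iqr
  inside <- values >= fence_low & values <= fence_high
  tibble(
    n = length(values),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    n_outliers = sum(!inside),
    outliers = list(sort(values[!inside]))
  )
}

#' Two-tailed Student t-test p-value
#'
#' Classical pooled-variance two-sample Student t-test (the form used for the
#' FRET positive/negative call), two-tailed; Welch's unequal-variance form is
#' available via `equal_variance = FALSE`. Degenerate zero-variance inputs
#' return the limiting p-value (1 for equal means, 0 otherwise) with a
#' warning instead of failing.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @param equal_variance Pooled-variance Student form (default) or Welch.
#' @return The p-value.
#' @export
#' @examples
#' students_t_two_tailed(rnorm(10), rnorm(10, 2))
students_t_two_tailed <- function(a, b, equal_variance = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("both samples need n >= 2.")
  }
  tryCatch(
    t.test(a, b, var.equal = equal_variance)$p.value,
    error = function(e) {
      # essentially constant data: limiting p-value
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        return(1)
      }
      warn("zero pooled variance with unequal means; returning p = 0 limit.")
      0
    }
  )
}

#' Ordinary least-squares trend with R-squared
#'
#' Fits `y = intercept + slope * x` and reports the coefficient of
#' determination `r_squared = 1 - SSres / SStot`, the trendline statistic
#' quoted on intensity-vs-intensity scatter plots.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' linear_trend_r2(1:10, 2 * (1:10) + rnorm(10, 0, 0.1))
linear_trend_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("need at least 3 points.")
  if (sd(x) == 0) abort("`x` is constant; trend undefined.")
  fit <- lm(y ~ x)
  ssres <- sum(resid(fit)^2)
  sstot <- sum((y - mean(y))^2)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (sstot > 0) 1 - ssres / sstot else 0,
    n = length(x)
  )
}

#' Normalize intensities so the data-set maximum is 1
#'
#' The display normalization used for pooled SPB intensity distributions:
#' every value is divided by the maximum of the data set.
#'
#' @param values Numeric vector with a positive maximum.
#' @return `values / max(values)`; order (and argmax) preserved.
#' @export
#' @examples
#' normalize_max_to_one(c(2, 4, 8))
normalize_max_to_one <- function(values) {
  if (!is.numeric(values) || length(values) == 0 || any(!is.finite(values))) {
    abort("`values` must be non-empty finite numeric.")
  }
  m <- max(values)
  if (m <= 0) abort("maximum must be > 0 to normalize.")
  values / m
}

#' Classify the two poles of a cell as SPB1 (strong) and SPB2 (weak)
#'
#' Within one cell the pole with the stronger fluorescence signal is SPB1 and
#' the weaker SPB2. Ties keep the input order and are flagged.
#'
#' @param intensity_a,intensity_b Non-negative intensities of the two poles
#'   in acquisition order.
#' @return A tibble with `spb1`, `spb2`, `spb1_was_first`, `tie`.
#' @export
#' @examples
#' classify_spb_pair(3, 5)
classify_spb_pair <- function(intensity_a, intensity_b) {
  assert_number(intensity_a, "intensity_a", lower = 0)
  assert_number(intensity_b, "intensity_b", lower = 0)
  tie <- intensity_a == intensity_b
  first_is_strong <- intensity_a >= intensity_b
  tibble(
    spb1 = if (first_is_strong) intensity_a else intensity_b,
    spb2 = if (first_is_strong) intensity_b else intensity_a,
    spb1_was_first = first_is_strong,
    tie = tie
  )
}

#' Classify every cell of a two-SPB intensity table
#'
#' Applies [classify_spb_pair()] per cell and optionally rescales all
#' intensities so the data-set maximum is 1 (the pooled display convention).
#'
#' @param data Tibble with columns `cell_id` and `intensity`, exactly two
#'   rows per cell (e.g. [simulate_spb_intensity_table()]).
#' @param normalize Apply [normalize_max_to_one()] across the whole table.
#' @return A tibble with one row per cell: `cell_id`, `spb1`, `spb2`, `tie`.
#' @export
classify_spb_table <- function(data, normalize = FALSE) {
  if (!all(c("cell_id", "intensity") %in% names(data))) {
    abort("`data` must have `cell_id` and `intensity` columns.")
  }
  counts <- table(data$cell_id)
  if (any(counts != 2)) {
    abort("every cell must have exactly 2 intensity rows.")
  }
  values <- data$intensity
  if (normalize) values <- normalize_max_to_one(values)
  tab <- dplyr::mutate(data, .norm_intensity = values)
  tab |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      classify_spb_pair(df$.norm_intensity[1], df$.norm_intensity[2])[
        , c("spb1", "spb2", "tie")]
    }) |>
    dplyr::ungroup()
}

#' Score anaphase duration from a spindle-length trace
#'
#' Anaphase duration is the time between the onset of the rapid
#' spindle-elongation phase and spindle breakdown. Onset is the first time
#' the centered sliding-window elongation rate exceeds
#' `rate_threshold_um_per_min`; breakdown is the first subsequent time the
#' length drops below `collapse_fraction` times the running maximum length.
#' Traces without a detectable onset or breakdown return a missing duration
#' with a reason (`"no onset"` / `"no breakdown"`); a trace with onset but no
#' breakdown is censored at the end of observation (`censored_at_min`),
#' mirroring how arrested cells are reported as "> span" rather than given a
#' duration.
#'
#' @param trace Tibble with `time_min` and `length_um` for one cell,
#'   strictly increasing time.
#' @param rate_threshold_um_per_min Elongation-rate threshold defining onset.
#' @param collapse_fraction Fraction of the running plateau below which the
#'   spindle is considered broken down.
#' @return A one-row tibble: `onset_min`, `breakdown_min`, `duration_min`,
#'   `censored_at_min`, `status` (`"ok"`, `"no onset"`, `"no breakdown"`).
#' @export
#' @examples
#' traces <- simulate_spindle_traces(spindle_sim_config(n_cells = 1, seed = 5))
#' anaphase_duration(traces)
anaphase_duration <- function(trace, rate_threshold_um_per_min = 0.5,
                              collapse_fraction = 0.5) {
  assert_number(rate_threshold_um_per_min, "rate_threshold_um_per_min",
                lower = 0, strict_lower = TRUE)
  assert_number(collapse_fraction, "collapse_fraction", lower = 0, upper = 1)
  if (!all(c("time_min", "length_um") %in% names(trace))) {
    abort("trace must have `time_min` and `length_um` columns.")
  }
  t <- trace$time_min
  l <- trace$length_um
  if (any(diff(t) <= 0)) abort("`time_min` must be strictly increasing.")
  n <- length(t)
  if (n < 5) abort("trace too short to score.")

  # centered 3-frame sliding-window rate
  rate <- rep(NA_real_, n)
  rate[2:(n - 1)] <- (l[3:n] - l[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])

  onset_idx <- which(rate > rate_threshold_um_per_min)[1]
  if (is.na(onset_idx)) {
    return(tibble(onset_min = NA_real_, breakdown_min = NA_real_,
                  duration_min = NA_real_, censored_at_min = NA_real_,
                  status = "no onset"))
  }
  onset <- t[onset_idx]

  run_max <- cummax(l)
  after <- seq(onset_idx + 1L, n)
  broke <- after[l[after] < collapse_fraction * run_max[after - 1L]]
  if (length(broke) == 0L) {
    return(tibble(onset_min = onset, breakdown_min = NA_real_,
                  duration_min = NA_real_, censored_at_min = t[n] - onset,
                  status = "no breakdown"))
  }
  breakdown <- t[broke[1]]
  tibble(onset_min = onset, breakdown_min = breakdown,
         duration_min = breakdown - onset, censored_at_min = NA_real_,
         status = "ok")
}

#' Score anaphase durations for a set of spindle traces
#'
#' @param traces Long tibble with `cell_id`, `time_min`, `length_um`
#'   (e.g. [simulate_spindle_traces()]).
#' @inheritParams anaphase_duration
#' @return One row per cell with the [anaphase_duration()] fields.
#' @export
score_spindle_traces <- function(traces, rate_threshold_um_per_min = 0.5,
                                 collapse_fraction = 0.5) {
  if (!"cell_id" %in% names(traces)) {
    abort("`traces` must have a `cell_id` column.")
  }
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      anaphase_duration(df, rate_threshold_um_per_min, collapse_fraction)
    }) |>
    dplyr::ungroup()
}
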
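#' Simulate spindle-length time-lapse traces
#'
#' Each trace follows the canonical anaphase trajectory of a budding-yeast
#' spindle: a metaphase plateau, linear rapid elongation starting at a drawn
#' onset time, an anaphase plateau at full length, and an abrupt collapse
#' (spindle breakdown, the read-out of mitotic exit) at `onset + duration`.
#' Onset and duration are drawn per cell from normal distributions; durations
#' are truncated below so breakdown is always after onset.
#'
#' @param config A [spindle_sim_config()].
#' @return A tibble of class `spindle_trace_set` with columns `cell_id`,
#'   `time_min`, `length_um`. Attribute `truth` holds a tibble of
#'   ground-truth `onset_min`, `breakdown_min`, `duration_min` per cell.
#' @seealso [anaphase_duration()], [score_spindle_traces()]
#' @export
#' @examples
#' traces <- simulate_spindle_traces(spindle_sim_config(n_cells = 3, seed = 2))
#' attr(traces, "truth")
simulate_spindle_traces <- function(config) {
  if (!inherits(config, "spindle_sim_config")) {
    abort("`config` must be created with spindle_sim_config().")
  }
  set.seed(config$seed)

  n <- config$n_cells
  onset <- pmax(rnorm(n, config$onset_mean_min, config$onset_sd_min),
                config$sampling_interval_min)
  duration <- pmax(rnorm(n, config$duration_mean_min, config$duration_sd_min),
                   config$min_duration_min)
  breakdown <- onset + duration

  times <- seq(0, config$total_time_min, by = config$sampling_interval_min)
  elongation_span <- (config$plateau_length_um - config$metaphase_length_um) /
    config$elongation_rate_um_min

  traces <- purrr::map(seq_len(n), function(i) {
    len <- spindle_length_profile(
      times, onset[i], breakdown[i], elongation_span,
      config$metaphase_length_um, config$plateau_length_um,
      config$elongation_rate_um_min, config$collapsed_length_um
    )
    if (config$length_noise_sd_um > 0) {
      len <- pmax(len + rnorm(length(len), sd = config$length_noise_sd_um), 0)
    }
    tibble(cell_id = sprintf("cell_%03d", i), time_min = times, length_um = len)
  })

  res <- dplyr::bind_rows(traces)
  attr(res, "truth") <- tibble(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    onset_min = onset,
    breakdown_min = breakdown,
    duration_min = duration
  )
  class(res) <- c("spindle_trace_set", class(res))
  res
}

# Piecewise noiseless length profile. Elongation is clipped at the plateau;
# if breakdown arrives before the plateau is reached the spindle collapses
# from whatever length it attained.
spindle_length_profile <- function(t, onset, breakdown, elongation_span,
                                   l0, l1, rate, l_collapsed) {
  len <- ifelse(
    t < onset, l0,
    ifelse(t < breakdown, pmin(l0 + rate * (t - onset), l1), l_collapsed)
  )
  len
}
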
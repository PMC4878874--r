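#' Simulate a FRAP spot-intensity trace
#'
#' Produces a fluorescence trace around a photobleaching event: a pre-bleach
#' plateau at `intensity_scale`, an instantaneous drop by `bleach_depth` at
#' the bleach frame, and single-exponential recovery
#' `I(t) = I_bleach + (I_plateau - I_bleach) (1 - exp(-k t))` with `t`
#' measured from the first post-bleach frame. The recovery plateau
#' `1 - immobile_fraction * bleach_depth` (relative to pre-bleach) encodes the
#' immobile pool. Additive Gaussian noise is applied to every frame.
#'
#' @param config A [frap_sim_config()].
#' @param trace_id Identifier stored in the `trace_id` column.
#' @return A tibble of class `frap_trace` with columns `trace_id`, `frame`,
#'   `time_s` (0 at the first post-bleach frame), `intensity` and `phase`
#'   (`"pre"`/`"post"`). Attributes: `bleach_index` (row of the first
#'   post-bleach frame) and `truth` (list with the ground-truth `k_per_s`,
#'   `t_half_s`, `immobile_fraction`, `bleach_depth`).
#' @seealso [simulate_frap_traces()], [fit_single_exponential()]
#' @export
simulate_frap_trace <- function(config, trace_id = "trace_1") {
  if (!inherits(config, "frap_sim_config")) {
    abort("`config` must be created with frap_sim_config().")
  }
  set.seed(config$seed)
  simulate_frap_trace_impl(config, trace_id)
}

#' Simulate several FRAP traces on a common time grid
#'
#' @param config A [frap_sim_config()]; its seed controls the whole set.
#' @param n Number of traces.
#' @return A tibble of class `frap_trace` stacking `n` traces
#'   (`trace_id = "trace_001"` ...), with the same attributes as
#'   [simulate_frap_trace()].
#' @export
#' @examples
#' traces <- simulate_frap_traces(frap_sim_config(seed = 3), n = 5)
#' dplyr::count(traces, trace_id)
simulate_frap_traces <- function(config, n = 20L) {
  if (!inherits(config, "frap_sim_config")) {
    abort("`config` must be created with frap_sim_config().")
  }
  assert_number(n, "n", lower = 0, strict_lower = TRUE, integerish = TRUE)
  set.seed(config$seed)
  out <- purrr::map(seq_len(n), function(i) {
    simulate_frap_trace_impl(config, sprintf("trace_%03d", i))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "bleach_index") <- attr(out[[1]], "bleach_index")
  attr(res, "truth") <- attr(out[[1]], "truth")
  class(res) <- c("frap_trace", class(res))
  res
}

# Core generator; assumes RNG state is already set by the caller.
simulate_frap_trace_impl <- function(config, trace_id) {
  n_pre <- config$pre_bleach_frames
  n_post <- config$post_bleach_frames
  dt <- config$frame_interval_s

  i_pre <- config$intensity_scale
  i_bleach <- i_pre * (1 - config$bleach_depth)
  i_plateau <- i_pre * (1 - config$immobile_fraction * config$bleach_depth)

  t_post <- (seq_len(n_post) - 1) * dt
  recovery <- if (config$off_rate_per_s > 0) {
    i_bleach + (i_plateau - i_bleach) * (1 - exp(-config$off_rate_per_s * t_post))
  } else {
    rep(i_bleach, n_post)
  }

  expected <- c(rep(i_pre, n_pre), recovery)
  intensity <- expected +
    rnorm(length(expected), sd = config$noise_sd * config$intensity_scale)

  time_s <- c(-(rev(seq_len(n_pre))) * dt, t_post)
  res <- tibble(
    trace_id = trace_id,
    frame = seq_along(expected),
    time_s = time_s,
    intensity = intensity,
    phase = rep(c("pre", "post"), c(n_pre, n_post))
  )
  attr(res, "bleach_index") <- n_pre + 1L
  attr(res, "truth") <- list(
    k_per_s = config$off_rate_per_s,
    t_half_s = config$t_half_s,
    immobile_fraction = config$immobile_fraction,
    bleach_depth = config$bleach_depth
  )
  class(res) <- c("frap_trace", class(res))
  res
}
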
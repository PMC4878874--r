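#' Normalize a FRAP trace to its pre-bleach level
#'
#' Divides intensities by the pre-bleach mean so the pre-bleach plateau is
#' ~1. If a reference (unbleached control) trace is supplied it is normalized
#' the same way and the trace is divided frame-wise by it, which cancels
#' acquisition bleaching shared by both.
#'
#' @param trace Tibble with columns `time_s` and `intensity` (e.g. from
#'   [simulate_frap_trace()]).
#' @param bleach_index Row index of the first post-bleach frame; defaults to
#'   the `bleach_index` attribute of the trace.
#' @param reference Optional numeric vector of reference intensities, same
#'   length as the trace.
#' @return The trace with `intensity` normalized (and a `reference_corrected`
#'   attribute if a reference was applied).
#' @export
normalize_trace <- function(trace, bleach_index = NULL, reference = NULL) {
  bleach_index <- bleach_index %||% attr(trace, "bleach_index")
  check_trace(trace, bleach_index)
  if (bleach_index <= 3) {
    abort("need at least 3 pre-bleach frames to normalize.")
  }
  pre <- trace$intensity[seq_len(bleach_index - 1L)]
  pre_mean <- mean(pre)
  if (!is.finite(pre_mean) || pre_mean <= 0) {
    abort("pre-bleach mean intensity must be > 0.")
  }
  out <- trace
  out$intensity <- trace$intensity / pre_mean
  if (!is.null(reference)) {
    if (length(reference) != nrow(trace)) {
      abort("`reference` must have one value per frame of the trace.")
    }
    ref_pre <- mean(reference[seq_len(bleach_index - 1L)])
    if (!is.finite(ref_pre) || ref_pre <= 0) {
      abort("reference pre-bleach mean must be > 0.")
    }
    out$intensity <- out$intensity / (reference / ref_pre)
    attr(out, "reference_corrected") <- TRUE
  }
  attr(out, "bleach_index") <- bleach_index
  out
}

#' Fit a single-exponential recovery to a FRAP trace
#'
#' Least-squares fit of `I(t) = c + a (1 - exp(-k t))` to the post-bleach
#' frames, with time measured from the first post-bleach frame ("time zero is
#' the first image taken after photobleaching"). The fit is multi-started
#' over `k` in `{0.01, 0.05, 0.1, 0.5, 1}` per second and the lowest-residual
#' solution kept, because single-start exponential fits are
#' initialization-sensitive. Optimizer failure yields `converged = FALSE`
#' rather than an error; fits with `k` below `k_floor` are reported with an
#' infinite half-time ("no recovery").
#'
#' @param trace Tibble with `time_s` and `intensity`. Intensities are
#'   expected on the normalized scale (see [normalize_trace()]); the trace is
#'   normalized automatically when its pre-bleach mean is not ~1.
#' @param bleach_index Row of the first post-bleach frame (defaults to the
#'   trace attribute).
#' @param k_starts Multi-start grid for `k`, per second.
#' @param k_floor Rates below this (per second) are reported as no recovery
#'   (`t_half_s = Inf`).
#' @param normalize Normalize the trace first (default `TRUE`).
#' @return An object of class `frap_fit` with fields `k_per_s`, `t_half_s`,
#'   `plateau_fraction` (fitted asymptote `c + a`), `bleach_depth_fraction`
#'   (`1 - c`), `mobile_fraction` (`a / (1 - c)`), `r_squared`, `converged`,
#'   `n_post`, and the data/fitted curve for plotting.
#' @seealso [tidy.frap_fit()], [glance.frap_fit()], [autoplot.frap_fit()]
#' @export
#' @examples
#' tr <- simulate_frap_trace(frap_sim_config(noise_sd = 0, seed = 1))
#' fit_single_exponential(tr)
fit_single_exponential <- function(trace, bleach_index = NULL,
                                   k_starts = c(0.01, 0.05, 0.1, 0.5, 1),
                                   k_floor = 1e-3, normalize = TRUE) {
  bleach_index <- bleach_index %||% attr(trace, "bleach_index")
  check_trace(trace, bleach_index)
  n_post <- nrow(trace) - bleach_index + 1L
  if (n_post < 5) {
    abort("need at least 5 post-bleach frames to fit.")
  }
  if (normalize) {
    trace <- normalize_trace(trace, bleach_index)
  }

  post <- trace[bleach_index:nrow(trace), ]
  t <- post$time_s - post$time_s[1]
  y <- post$intensity

  c0 <- y[1]
  a0 <- max(mean(tail(y, max(3L, length(y) %/% 5))) - c0, 1e-6)

  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c + a * (1 - exp(-k * t)),
        start = list(c = c0, a = a0, k = k0),
        lower = c(c = -Inf, a = -Inf, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }

  pre_level <- mean(trace$intensity[seq_len(bleach_index - 1L)])
  if (is.null(best)) {
    return(new_frap_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                        NA_real_, FALSE, n_post, trace, bleach_index, NULL))
  }

  cf <- coef(best$fit)
  k <- unname(cf["k"])
  a <- unname(cf["a"])
  c_ <- unname(cf["c"])
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - best$rss / sstot else NA_real_
  depth <- pre_level - c_
  mobile <- if (depth > 0) a / depth else NA_real_
  # "no recovery": rate below the floor, or a negligible fitted recovery
  # amplitude (k is unidentifiable on a flat trace)
  no_recovery <- k < k_floor || a <= 0 ||
    (is.finite(mobile) && mobile < 1e-3)
  t_half <- if (no_recovery) Inf else log(2) / k

  new_frap_fit(
    k_per_s = k, t_half_s = t_half,
    plateau_fraction = c_ + a,
    bleach_depth_fraction = depth,
    mobile_fraction = mobile,
    r_squared = r2, converged = TRUE, n_post = n_post,
    trace = trace, bleach_index = bleach_index,
    fitted_curve = tibble(time_s = post$time_s,
                          fitted = c_ + a * (1 - exp(-k * t)))
  )
}

new_frap_fit <- function(k_per_s, t_half_s, plateau_fraction,
                         bleach_depth_fraction, mobile_fraction, r_squared,
                         converged, n_post, trace, bleach_index, fitted_curve) {
  structure(
    list(
      k_per_s = k_per_s,
      t_half_s = t_half_s,
      plateau_fraction = plateau_fraction,
      bleach_depth_fraction = bleach_depth_fraction,
      mobile_fraction = mobile_fraction,
      r_squared = r_squared,
      converged = converged,
      n_post = n_post,
      trace = trace,
      bleach_index = bleach_index,
      fitted_curve = fitted_curve
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> single-exponential recovery\n")
  if (!isTRUE(x$converged)) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  k = %.4g /s   t-half = %.4g s   mobile fraction = %.3f   R^2 = %.4f\n",
              x$k_per_s, x$t_half_s, x$mobile_fraction, x$r_squared))
  invisible(x)
}

#' Fit every trace of a multi-trace FRAP data set
#'
#' @param traces Long tibble with columns `trace_id`, `time_s`, `intensity`
#'   (e.g. [simulate_frap_traces()]).
#' @inheritParams fit_single_exponential
#' @return A tibble with one row per trace: `trace_id`, `k_per_s`,
#'   `t_half_s`, `mobile_fraction`, `plateau_fraction`, `r_squared`,
#'   `converged`.
#' @export
fit_frap_traces <- function(traces, bleach_index = NULL, ...) {
  bleach_index <- bleach_index %||% attr(traces, "bleach_index")
  if (!"trace_id" %in% names(traces)) {
    abort("`traces` must have a `trace_id` column.")
  }
  traces |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_single_exponential(df, bleach_index = bleach_index, ...)
      tibble(
        k_per_s = fit$k_per_s, t_half_s = fit$t_half_s,
        mobile_fraction = fit$mobile_fraction,
        plateau_fraction = fit$plateau_fraction,
        r_squared = fit$r_squared, converged = fit$converged
      )
    }) |>
    dplyr::ungroup()
}

#' Average aligned FRAP traces
#'
#' Per-timepoint mean and standard deviation across traces that share a
#' common time grid aligned at the bleach frame. The average curve is the
#' display convention of FRAP figures and can itself be fitted with
#' [fit_single_exponential()].
#'
#' @param traces Long tibble with `trace_id`, `time_s`, `intensity`.
#' @param normalize Normalize each trace to its pre-bleach mean first.
#' @param bleach_index Row of the first post-bleach frame within each trace.
#' @return A tibble `time_s`, `intensity` (the per-timepoint mean),
#'   `sd_intensity`, `n`, carrying the `bleach_index` attribute so it can be
#'   passed straight to [fit_single_exponential()].
#' @export
average_recovery_curve <- function(traces, normalize = TRUE,
                                   bleach_index = NULL) {
  bleach_index <- bleach_index %||% attr(traces, "bleach_index")
  if (!"trace_id" %in% names(traces)) {
    abort("`traces` must have a `trace_id` column.")
  }
  split_traces <- split(traces, traces$trace_id)
  grids <- purrr::map(split_traces, ~ .x$time_s)
  ref_grid <- grids[[1]]
  same <- purrr::map_lgl(grids, ~ length(.x) == length(ref_grid) &&
                           all(abs(.x - ref_grid) < 1e-9))
  if (!all(same)) {
    abort("traces are not on a common time grid; align them before averaging.")
  }
  if (normalize) {
    split_traces <- purrr::map(split_traces, normalize_trace,
                               bleach_index = bleach_index)
  }
  mat <- do.call(cbind, purrr::map(split_traces, ~ .x$intensity))
  out <- tibble(
    time_s = ref_grid,
    intensity = rowMeans(mat),
    sd_intensity = apply(mat, 1, sd),
    n = ncol(mat)
  )
  attr(out, "bleach_index") <- bleach_index
  out
}

check_trace <- function(trace, bleach_index) {
  if (!all(c("time_s", "intensity") %in% names(trace))) {
    abort("trace must have `time_s` and `intensity` columns.")
  }
  if (is.null(bleach_index) || !is.numeric(bleach_index) ||
      bleach_index < 2 || bleach_index > nrow(trace)) {
    abort("valid `bleach_index` required (first post-bleach frame).")
  }
  if (any(diff(trace$time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  invisible(trace)
}
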
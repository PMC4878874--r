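test_that("pre-bleach normalization rescales to unity and references cancel", {
  tr <- tibble::tibble(time_s = c(-3, -2, -1, 0, 1, 2, 3),
                       intensity = c(100, 100, 100, 20, 30, 40, 45))
  out <- normalize_trace(tr, bleach_index = 4)
  expect_equal(mean(out$intensity[1:3]), 1)
  expect_equal(out$intensity[4], 0.2)

  # trace and reference both halved by acquisition bleaching -> flat ratio
  decay <- 0.5^(seq(0, 6) / 6)
  tr2 <- tibble::tibble(time_s = -3:3, intensity = 100 * decay)
  out2 <- normalize_trace(tr2, bleach_index = 4, reference = 80 * decay)
  expect_equal(out2$intensity, rep(1, 7), tolerance = 1e-12)

  expect_error(normalize_trace(
    tibble::tibble(time_s = -3:3, intensity = c(0, 0, 0, 1, 1, 1, 1)),
    bleach_index = 4
  ), "pre-bleach mean")
})

test_that("noiseless traces recover rate and plateau almost exactly", {
  cfg <- frap_sim_config(off_rate_per_s = log(2) / 11, noise_sd = 0, seed = 1)
  tr <- simulate_frap_trace(cfg)
  fit <- fit_single_exponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$t_half_s, 11, tolerance = 1e-3)
  expect_equal(fit$k_per_s, log(2) / 11, tolerance = 1e-4)
  # normalized plateau = 1 - immobile_fraction * bleach_depth
  expect_equal(fit$plateau_fraction, 1 - cfg$immobile_fraction * cfg$bleach_depth,
               tolerance = 1e-4)
  expect_equal(fit$mobile_fraction, 1 - cfg$immobile_fraction, tolerance = 1e-3)
})

test_that("an immobile pool gives a flat post-bleach trace and no half-time", {
  cfg <- frap_sim_config(off_rate_per_s = 0, immobile_fraction = 1,
                         noise_sd = 0, seed = 2)
  tr <- simulate_frap_trace(cfg)
  post <- tr$intensity[tr$phase == "post"]
  expect_equal(post, rep(post[1], length(post)))
  fit <- fit_single_exponential(tr)
  expect_true(!fit$converged || is.infinite(fit$t_half_s))
})

test_that("a fully mobile pool recovers to the pre-bleach plateau", {
  cfg <- frap_sim_config(bleach_depth = 1, immobile_fraction = 0,
                         noise_sd = 0, post_bleach_frames = 600L, seed = 3)
  tr <- simulate_frap_trace(cfg)
  expect_equal(tail(tr$intensity, 1), 1, tolerance = 1e-3)
  fit <- fit_single_exponential(tr)
  expect_equal(fit$plateau_fraction, 1, tolerance = 1e-3)
  expect_equal(fit$mobile_fraction, 1, tolerance = 1e-3)
})

test_that("mean fitted half-time is accurate at moderate noise", {
  traces <- simulate_frap_traces(fixture_config("kar9_misaligned_frap", seed = 11),
                                 n = 20)
  fits <- fit_frap_traces(traces)
  expect_true(all(fits$converged))
  expect_lt(abs(mean(fits$t_half_s) - 11) / 11, 0.15)
})

test_that("fitting is invariant to an overall intensity scale", {
  cfg <- frap_sim_config(seed = 6)
  tr <- simulate_frap_trace(cfg)
  scaled <- tr
  scaled$intensity <- 37.5 * tr$intensity
  f1 <- fit_single_exponential(tr)
  f2 <- fit_single_exponential(scaled)
  # identical up to optimizer convergence tolerance
  expect_equal(f2$k_per_s, f1$k_per_s, tolerance = 1e-6)
  expect_equal(f2$t_half_s, f1$t_half_s, tolerance = 1e-6)
  expect_equal(f2$mobile_fraction, f1$mobile_fraction, tolerance = 1e-6)
})

test_that("average recovery curves pool aligned traces correctly", {
  cfg <- frap_sim_config(noise_sd = 0, seed = 4)
  tr <- simulate_frap_trace(cfg)
  stack <- dplyr::bind_rows(
    dplyr::mutate(tr, trace_id = "a"),
    dplyr::mutate(tr, trace_id = "b")
  )
  attr(stack, "bleach_index") <- attr(tr, "bleach_index")
  avg <- average_recovery_curve(stack)
  expect_equal(avg$intensity, normalize_trace(tr)$intensity)
  expect_equal(avg$sd_intensity, rep(0, nrow(avg)))

  # n-1 standard deviation at a single timepoint
  two <- tibble::tibble(
    trace_id = rep(c("a", "b"), each = 5),
    time_s = rep(c(-2, -1, 0, 1, 2), 2),
    intensity = c(1, 1, 0.1, 0.2, 0.2, 1, 1, 0.1, 0.4, 0.4)
  )
  avg2 <- average_recovery_curve(two, normalize = FALSE, bleach_index = 3)
  expect_equal(avg2$intensity[4], 0.3)
  expect_equal(avg2$sd_intensity[4], sd(c(0.2, 0.4)))
  expect_equal(round(avg2$sd_intensity[4], 4), 0.1414)

  # mismatched grids are an error
  bad <- dplyr::mutate(two, time_s = ifelse(trace_id == "b", time_s * 2, time_s))
  expect_error(average_recovery_curve(bad, normalize = FALSE, bleach_index = 3),
               "common time grid")
})

test_that("fitting the averaged curve is less biased than typical single fits", {
  k_true <- log(2) / 11
  traces <- simulate_frap_traces(frap_sim_config(noise_sd = 0.15, seed = 19), n = 50)
  fits <- fit_frap_traces(traces)
  avg_fit <- fit_single_exponential(average_recovery_curve(traces))
  bias_avg <- abs(avg_fit$k_per_s - k_true)
  bias_med <- median(abs(fits$k_per_s - k_true))
  expect_lt(bias_avg, bias_med)
})

test_that("r-squared stays in range and degrades with noise", {
  sds <- c(0.01, 0.05, 0.2)
  mean_r2 <- vapply(seq_along(sds), function(i) {
    traces <- simulate_frap_traces(frap_sim_config(noise_sd = sds[i], seed = 30 + i),
                                   n = 15)
    fits <- fit_frap_traces(traces)
    expect_true(all(fits$r_squared[fits$converged] >= 0 &
                      fits$r_squared[fits$converged] <= 1))
    mean(fits$r_squared, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("invalid traces are rejected", {
  tr <- simulate_frap_trace(frap_sim_config(seed = 8))
  bad <- tr
  bad$time_s <- rev(bad$time_s)
  expect_error(fit_single_exponential(bad), "increasing")
  short <- tr[1:12, ]
  expect_error(fit_single_exponential(short, bleach_index = 11), "post-bleach")
})

test_that("frap_fit tidiers expose rate, half-time and mobile fraction", {
  fit <- fit_single_exponential(simulate_frap_trace(frap_sim_config(noise_sd = 0,
                                                                    seed = 9)))
  td <- tidy(fit)
  expect_true(all(c("k_per_s", "t_half_s", "mobile_fraction") %in% td$term))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
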
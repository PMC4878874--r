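test_that("box-whisker summary reproduces the worked example", {
  bw <- box_whisker_summary(c(1:9, 100))
  expect_equal(bw$q1, 3.25)
  expect_equal(bw$q3, 7.75)
  expect_equal(bw$median, 5.5)
  expect_equal(bw$outliers[[1]], 100)
  expect_equal(bw$whisker_high, 9)
  expect_equal(bw$whisker_low, 1)
})

test_that("degenerate and symmetric inputs behave", {
  flat <- box_whisker_summary(rep(4.2, 6))
  expect_equal(flat$q3 - flat$q1, 0)
  expect_equal(flat$n_outliers, 0L)
  expect_equal(flat$whisker_low, 4.2)
  expect_equal(flat$whisker_high, 4.2)

  sym <- box_whisker_summary(c(-3, -1, 0, 1, 3))
  expect_equal(sym$median - sym$q1, sym$q3 - sym$median)

  expect_error(box_whisker_summary(c(1, 2, 3)), "at least 4")
})

test_that("box-whisker agrees with a brute-force pass and partitions the data", {
  set.seed(12)
  for (i in 1:25) {
    x <- round(rnorm(sample(4:60, 1), sd = sample(c(1, 10), 1)), 2)
    bw <- box_whisker_summary(x)
    q1 <- oracle_quartile(x, 0.25)
    q3 <- oracle_quartile(x, 0.75)
    expect_equal(bw$q1, q1)
    expect_equal(bw$q3, q3)
    fence_lo <- q1 - 1.5 * (q3 - q1)
    fence_hi <- q3 + 1.5 * (q3 - q1)
    inside <- x[x >= fence_lo & x <= fence_hi]
    outside <- x[x < fence_lo | x > fence_hi]
    expect_equal(bw$whisker_low, min(inside))
    expect_equal(bw$whisker_high, max(inside))
    expect_equal(bw$outliers[[1]], sort(outside))
    # union of whisker-bounded data and outliers is the input multiset
    expect_equal(sort(c(inside, outside)), sort(x))
  }
})

test_that("Student t-test matches the textbook formula and is symmetric", {
  expect_equal(students_t_two_tailed(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(students_t_two_tailed(c(1, 2, 3), c(101, 102, 103)), 1e-6)
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    expect_equal(students_t_two_tailed(a, b), oracle_student_p(a, b),
                 tolerance = 1e-12)
    expect_equal(students_t_two_tailed(a, b), students_t_two_tailed(b, a),
                 tolerance = 1e-12)
  }
  expect_error(students_t_two_tailed(1, c(1, 2)), "n >= 2")
  expect_warning(p <- students_t_two_tailed(c(1, 1), c(2, 2)), "p = 0")
  expect_equal(p, 0)
})

test_that("trend fitting matches the normal equations", {
  x <- 1:10
  exact <- linear_trend_r2(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- linear_trend_r2(x, rep(3, 10))
  expect_equal(flat$r_squared, 0)

  set.seed(5)
  for (i in 1:10) {
    xx <- rnorm(20)
    yy <- 1.5 * xx + rnorm(20, sd = 0.5)
    got <- linear_trend_r2(xx, yy)
    want <- oracle_ols(xx, yy)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    # r-squared invariant under affine transforms of x and y
    shifted <- linear_trend_r2(3 * xx - 7, -2 * yy + 11)
    expect_equal(shifted$r_squared, got$r_squared, tolerance = 1e-10)
  }
  expect_error(linear_trend_r2(rep(1, 5), rnorm(5)), "constant")
})

test_that("max-to-one normalization rescales without reordering", {
  expect_equal(normalize_max_to_one(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_max_to_one(1), 1)
  set.seed(6)
  x <- rexp(30)
  expect_equal(which.max(normalize_max_to_one(x)), which.max(x))
  expect_error(normalize_max_to_one(c(-2, -1)), "maximum")
})

test_that("SPB pairs are classified strong/weak with ties flagged", {
  a <- classify_spb_pair(5, 3)
  expect_equal(c(a$spb1, a$spb2), c(5, 3))
  b <- classify_spb_pair(3, 5)
  expect_equal(c(b$spb1, b$spb2), c(5, 3))
  expect_false(b$spb1_was_first)
  tie <- classify_spb_pair(4, 4)
  expect_true(tie$tie)
  expect_true(tie$spb1_was_first)  # tie keeps input order
})

test_that("simulated SPB tables have the configured asymmetry", {
  flat <- simulate_spb_intensity_table(10, asymmetry_ratio = 1, noise_cv = 0,
                                       seed = 4)
  per_cell <- split(flat$intensity, flat$cell_id)
  expect_true(all(vapply(per_cell, function(v) v[1] == v[2], logical(1))))
  cl_flat <- classify_spb_table(flat)
  expect_true(all(cl_flat$tie))

  tab <- simulate_spb_intensity_table(33, asymmetry_ratio = 3, noise_cv = 0.1,
                                      seed = 9)
  expect_true(all(table(tab$cell_id) == 2))
  expect_true(all(tab$intensity > 0))
  cl <- classify_spb_table(tab)
  expect_lt(abs(median(cl$spb1) / median(cl$spb2) - 3) / 3, 0.15)
  # classification recovers the ground-truth bright pole
  truth_bright <- tab$intensity[tab$true_label == "bright"]
  expect_equal(sort(cl$spb1), sort(truth_bright))

  norm <- classify_spb_table(tab, normalize = TRUE)
  expect_equal(max(c(norm$spb1, norm$spb2)), 1)
})

test_that("anaphase duration is the onset-to-breakdown interval", {
  times <- seq(0, 45, by = 1)
  mk_trace <- function(onset, breakdown) {
    len <- ifelse(times < onset, 1.5,
                  ifelse(times < breakdown, pmin(1.5 + (times - onset), 8), 0.5))
    tibble::tibble(time_min = times, length_um = len)
  }
  res <- anaphase_duration(mk_trace(10, 33))
  expect_equal(res$status, "ok")
  expect_lte(abs(res$duration_min - 23), 1)

  no_collapse <- tibble::tibble(
    time_min = times,
    length_um = ifelse(times < 10, 1.5, pmin(1.5 + (times - 10), 8))
  )
  censored <- anaphase_duration(no_collapse)
  expect_equal(censored$status, "no breakdown")
  expect_true(is.na(censored$duration_min))
  expect_false(is.na(censored$censored_at_min))

  flat <- tibble::tibble(time_min = times, length_um = rep(1.5, length(times)))
  expect_equal(anaphase_duration(flat)$status, "no onset")

  bad <- mk_trace(10, 33)
  bad$time_min <- rev(bad$time_min)
  expect_error(anaphase_duration(bad), "increasing")
})

test_that("the scorer recovers simulated durations without bias", {
  cfg <- spindle_sim_config(n_cells = 30, duration_mean_min = 23,
                            duration_sd_min = 4, seed = 14)
  traces <- simulate_spindle_traces(cfg)
  scores <- score_spindle_traces(traces)
  ok <- scores$duration_min[scores$status == "ok"]
  expect_gte(length(ok), 28)
  expect_true(all(ok > 0))
  se <- 4 / sqrt(length(ok))
  expect_lt(abs(mean(ok) - 23), 2 * se)
})
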
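test_that("background correction is subtraction, flagging negative results", {
  expect_equal(background_correct(100, 20), 80)
  expect_equal(background_correct(20, 20), 0)
  expect_warning(out <- background_correct(15, 20), "negative")
  expect_equal(out, -5)
})

test_that("percentage increase follows the de-quenching formula", {
  expect_equal(percent_increase(80, 92), 15)
  expect_equal(percent_increase(80, 80), 0)
  expect_equal(percent_increase(80, 76), -5)
  expect_error(percent_increase(0, 10), "fl_cor_pre")
  expect_error(percent_increase(-3, 10), "fl_cor_pre")
})

test_that("donor-median normalization zeroes the donor-only median", {
  out <- normalize_to_donor_median(c(15, 16, 17), c(1, 2, 3))
  expect_equal(out$e_da_norm, c(13, 14, 15))
  expect_equal(out$e_d_norm, c(-1, 0, 1))
  expect_equal(out$e_d_median, 2)
  # no-op when the control median is already zero
  same <- normalize_to_donor_median(c(1, 2), c(0, 0, 0))
  expect_equal(same$e_da_norm, c(1, 2))
  # property: median of normalized donor-only values is 0 -- exactly for odd
  # n (the median is one of the values), to rounding for even n (it is the
  # midpoint of two)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    e_d <- rnorm(n, mean = runif(1, -5, 5), sd = runif(1, 0, 4))
    out <- normalize_to_donor_median(rnorm(10), e_d)
    if (n %% 2 == 1) {
      expect_identical(median(out$e_d_norm), 0)
    } else {
      expect_lt(abs(median(out$e_d_norm)), 1e-12)
    }
  }
  expect_error(normalize_to_donor_median(c(1, 2), numeric(0)), "donor-only")
})

test_that("pair calls require both significance and a positive shift", {
  set.seed(8)
  d <- rnorm(30, 0, 3)
  da <- rnorm(30, 14, 3)
  pos <- classify_fret_pair(da, d)
  expect_true(pos$positive)
  expect_lt(pos$p_value, 0.01)
  expect_equal(pos$p_value, oracle_student_p(da, d), tolerance = 1e-12)

  same <- classify_fret_pair(d, d)
  expect_false(same$positive)

  # significant but in the wrong direction: de-quenching must be an increase
  below <- classify_fret_pair(d - 14, d)
  expect_lt(below$p_value, 0.01)
  expect_false(below$positive)
})

test_that("undersized groups are flagged, not crashed", {
  res <- classify_fret_pair(c(1, 2), c(0, 0, 1))
  expect_false(res$positive)
  expect_equal(res$flag, "insufficient_n")
  expect_true(is.na(res$p_value))
})

test_that("the image pipeline equals a spreadsheet-style recomputation", {
  cfg <- sim_config(apparent_efficiency_pct = 20, n_cells_DA = 4, n_cells_D = 4,
                    n_cells_bg = 2, seed = 13)
  set <- simulate_fret_image_set(cfg)
  res <- quantify_image_set(set)
  oracle <- oracle_fret_recompute(set, res$cells)
  expect_equal(res$efficiencies_DA_pct, oracle$e_da_norm, tolerance = 1e-9)
  expect_equal(res$efficiencies_D_pct, oracle$e_d_norm, tolerance = 1e-9)
  expect_equal(res$E_D_median, oracle$e_d_median, tolerance = 1e-9)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-9)
})

test_that("efficiencies are invariant to detector gain", {
  cfg <- tiny_fret_config(seed = 17)
  set <- simulate_fret_image_set(cfg)
  scaled <- set
  scaled$images <- lapply(set$images, function(cell) lapply(cell, function(m) 3.7 * m))
  res <- quantify_image_set(set)
  res_scaled <- quantify_image_set(scaled)
  expect_equal(res_scaled$efficiencies_DA_pct, res$efficiencies_DA_pct,
               tolerance = 1e-9)
  expect_equal(res_scaled$efficiencies_D_pct, res$efficiencies_D_pct,
               tolerance = 1e-9)
})

test_that("efficiencies are invariant to a constant offset on every image", {
  cfg <- tiny_fret_config(seed = 18)
  set <- simulate_fret_image_set(cfg)
  shifted <- set
  shifted$images <- lapply(set$images, function(cell) lapply(cell, function(m) m + 250))
  res <- quantify_image_set(set)
  res_shifted <- quantify_image_set(shifted)
  expect_equal(res_shifted$efficiencies_DA_pct, res$efficiencies_DA_pct,
               tolerance = 1e-9)
})

test_that("estimated efficiency increases monotonically with the configured one", {
  means <- vapply(c(5, 10, 20, 30), function(e) {
    cfg <- sim_config(apparent_efficiency_pct = e, n_cells_DA = 50,
                      n_cells_D = 40, n_cells_bg = 15, seed = 50 + e)
    mean(quantify_image_set(simulate_fret_image_set(cfg))$efficiencies_DA_pct)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("each shipped FRET fixture recovers its configured efficiency", {
  for (fx in c("spc42_cnm67", "tandem_bfa1", "donor_only")) {
    cfg <- fixture_config(fx, seed = 7)
    res <- quantify_image_set(simulate_fret_image_set(cfg))
    ci <- boot_ci(res$efficiencies_DA_pct, stat = mean)
    expect_lte(ci[1], cfg$apparent_efficiency_pct)
    expect_gte(ci[2], cfg$apparent_efficiency_pct)
  }
})

test_that("a donor-only population run as the pair is called negative", {
  cfg <- fixture_config("donor_only", seed = 23)
  res <- quantify_image_set(simulate_fret_image_set(cfg))
  expect_false(res$positive)
})

test_that("noiseless reference fixture yields exactly 14 percent", {
  res <- quantify_image_set(simulate_fret_image_set(noiseless_fret_config(14)))
  expect_equal(mean(res$efficiencies_DA_pct), 14, tolerance = 1e-6)
})

test_that("missing sample classes are reported by name", {
  set <- simulate_fret_image_set(tiny_fret_config(seed = 2))
  no_bg <- set
  keep <- set$manifest$class != "bg"
  no_bg$manifest <- set$manifest[keep, ]
  no_bg$images <- set$images[no_bg$manifest$cell_id]
  expect_error(quantify_image_set(no_bg), "'bg'")
  no_d <- set
  keep <- set$manifest$class != "D"
  no_d$manifest <- set$manifest[keep, ]
  no_d$images <- set$images[no_d$manifest$cell_id]
  expect_error(quantify_image_set(no_d), "donor-only")
})

test_that("tidy and glance summarize the pair result", {
  set.seed(4)
  res <- classify_fret_pair(rnorm(20, 10, 2), rnorm(20, 0, 2),
                            pair_name = "demo", e_d_median = 0.5)
  td <- tidy(res)
  expect_equal(td$group, c("DA", "D"))
  expect_equal(td$n, c(20L, 20L))
  gl <- glance(res)
  expect_equal(gl$pair_name, "demo")
  expect_true(gl$positive)
  expect_s3_class(autoplot(res), "ggplot")
})
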
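# Shared helpers: small configurations and independent oracle routines used
# across test files. Oracles deliberately avoid the package's code paths.

tiny_fret_config <- function(..., seed = 7) {
  sim_config(n_cells_DA = 5, n_cells_D = 5, n_cells_bg = 3, seed = seed, ...)
}

noiseless_fret_config <- function(e, ..., seed = 7) {
  sim_config(
    apparent_efficiency_pct = e, noise = FALSE,
    acquisition_bleach_per_frame = 0,
    n_cells_DA = 4, n_cells_D = 4, n_cells_bg = 2, seed = seed, ...
  )
}

# percentile bootstrap CI for any statistic
boot_ci <- function(values, stat = mean, n_boot = 2000, level = 0.99, seed = 99) {
  set.seed(seed)
  boots <- replicate(n_boot, stat(sample(values, replace = TRUE)))
  unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

# Independent quartiles by inclusive linear interpolation (spreadsheet rule):
# h = (n - 1) p + 1 on the sorted values.
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Independent two-sample pooled-variance two-tailed t-test via the textbook
# formula and the t CDF.
oracle_student_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

# Independent OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Brute-force spreadsheet-style FRET recomputation from images, reusing only
# the ROI centers chosen by the pipeline. All arithmetic is explicit loops.
oracle_fret_recompute <- function(image_set, cells, roi_half_width = 2) {
  roi_mean_loop <- function(img, r, c, h) {
    acc <- 0
    cnt <- 0
    for (i in (r - h):(r + h)) {
      for (j in (c - h):(c + h)) {
        acc <- acc + img[i, j]
        cnt <- cnt + 1
      }
    }
    acc / cnt
  }
  fl_pre <- numeric(0)
  fl_post <- numeric(0)
  cls <- character(0)
  full_mean_loop <- function(img) {
    acc <- 0
    for (i in seq_len(nrow(img))) {
      for (j in seq_len(ncol(img))) acc <- acc + img[i, j]
    }
    acc / (nrow(img) * ncol(img))
  }
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    imgs <- image_set$images[[row$cell_id]]
    if (row$class == "bg") {
      fl_pre <- c(fl_pre, full_mean_loop(imgs$donor_pre))
      fl_post <- c(fl_post, full_mean_loop(imgs$donor_post))
    } else {
      r <- round(row$roi_row)
      c <- round(row$roi_col)
      fl_pre <- c(fl_pre, roi_mean_loop(imgs$donor_pre, r, c, roi_half_width))
      fl_post <- c(fl_post, roi_mean_loop(imgs$donor_post, r, c, roi_half_width))
    }
    cls <- c(cls, row$class)
  }
  bg_pre <- mean(fl_pre[cls == "bg"])
  bg_post <- mean(fl_post[cls == "bg"])
  e <- 100 * ((fl_post - bg_post) - (fl_pre - bg_pre)) / (fl_pre - bg_pre)
  e_d <- e[cls == "D"]
  med <- median(e_d)
  list(
    e_da_norm = e[cls == "DA"] - med,
    e_d_norm = e_d - med,
    e_d_median = med,
    p_value = oracle_student_p(e[cls == "DA"] - med, e_d - med)
  )
}
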
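#' Background-correct a mean fluorescence intensity
#'
#' Subtracts the background ROI mean from a raw ROI mean,
#' `FL_cor = FL - FL_bg`. Negative corrected values are allowed (they occur
#' under noise) but flagged with a warning so exclusions can be audited.
#'
#' @param fl Raw mean fluorescence intensity (vectorized).
#' @param fl_bg Background mean fluorescence intensity.
#' @return `fl - fl_bg`.
#' @export
#' @examples
#' background_correct(100, 20)
background_correct <- function(fl, fl_bg) {
  if (!is.numeric(fl) || !is.numeric(fl_bg) || any(!is.finite(fl)) || any(!is.finite(fl_bg))) {
    abort("`fl` and `fl_bg` must be finite numeric values.")
  }
  out <- fl - fl_bg
  if (any(out < 0)) {
    warn(sprintf("%d background-corrected intensit%s negative.",
                 sum(out < 0), if (sum(out < 0) == 1) "y is" else "ies are"))
  }
  out
}

#' Percentage increase in corrected donor signal after acceptor photobleaching
#'
#' The per-cell de-quenching read-out:
#' `E = 100 * (FL_cor_post - FL_cor_pre) / FL_cor_pre`. Defined only for
#' positive pre-bleach corrected intensity; cells violating that are excluded
#' upstream, not imputed.
#'
#' @param fl_cor_pre,fl_cor_post Background-corrected donor ROI means before
#'   and after the acceptor bleach (vectorized).
#' @return Percentage increase (can be negative under noise).
#' @export
#' @examples
#' percent_increase(80, 92)
percent_increase <- function(fl_cor_pre, fl_cor_post) {
  if (any(!is.finite(fl_cor_pre)) || any(!is.finite(fl_cor_post))) {
    abort("corrected intensities must be finite.")
  }
  if (any(fl_cor_pre <= 0)) {
    abort("`fl_cor_pre` must be > 0; exclude such cells before calling percent_increase().")
  }
  100 * (fl_cor_post - fl_cor_pre) / fl_cor_pre
}

#' Normalize efficiencies to the donor-only median
#'
#' Corrects both distributions for the median of the donor-only control: each
#' value has `median(e_d)` subtracted (default), making the normalized
#' donor-only median exactly 0. This removes systematic donor-only effects
#' such as acquisition bleaching between the two donor exposures. A
#' division variant (`value / median`) is available but unstable when the
#' donor-only median is near zero.
#'
#' @param e_da,e_d Percentage-increase values for the donor+acceptor and
#'   donor-only samples.
#' @param method `"subtract"` (default) or `"divide"`.
#' @return A list with `e_da_norm`, `e_d_norm` and `e_d_median`.
#' @export
#' @examples
#' normalize_to_donor_median(c(15, 16, 17), c(1, 2, 3))
normalize_to_donor_median <- function(e_da, e_d, method = c("subtract", "divide")) {
  method <- match.arg(method)
  if (length(e_d) == 0L) {
    abort("donor-only sample required: `e_d` is empty, normalization impossible.")
  }
  m <- median(e_d)
  if (method == "subtract") {
    list(e_da_norm = e_da - m, e_d_norm = e_d - m, e_d_median = m)
  } else {
    if (abs(m) < .Machine$double.eps) {
      abort("donor-only median is 0; division normalization undefined (use method = 'subtract').")
    }
    list(e_da_norm = e_da / m, e_d_norm = e_d / m, e_d_median = m)
  }
}

#' Call a FRET pair positive or negative
#'
#' Compares the normalized donor+acceptor efficiency distribution against the
#' normalized donor-only control with a two-tailed Student t-test
#' (equal-variance by default; Welch behind `equal_variance = FALSE`). The
#' pair is called positive only if `p < alpha` *and* the donor+acceptor mean
#' exceeds the donor-only mean — de-quenching must be an increase.
#'
#' @param e_da_norm,e_d_norm Normalized efficiency values (percent).
#' @param alpha Significance level for the call (default 0.01).
#' @param equal_variance Use the classical pooled-variance Student t-test
#'   (`TRUE`, default) or Welch's form.
#' @param pair_name Label stored in the result.
#' @param e_d_median Donor-only median recorded during normalization
#'   (stored in the result; not used in the test).
#' @param cells Optional per-cell tibble carried through to the result.
#' @return An object of class `fret_pair_result`; see [tidy.fret_pair_result()]
#'   and [glance.fret_pair_result()]. If either group has fewer than 3 values
#'   the result is negative with `flag = "insufficient_n"` and `p_value = NA`.
#' @export
#' @examples
#' classify_fret_pair(rnorm(30, 14, 3), rnorm(30, 0, 3))
classify_fret_pair <- function(e_da_norm, e_d_norm, alpha = 0.01,
                               equal_variance = TRUE, pair_name = "pair",
                               e_d_median = NA_real_, cells = NULL) {
  assert_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  n_da <- length(e_da_norm)
  n_d <- length(e_d_norm)

  if (n_da < 3 || n_d < 3) {
    return(new_fret_pair_result(
      pair_name, e_da_norm, e_d_norm, e_d_median, p_value = NA_real_,
      positive = FALSE, alpha = alpha, flag = "insufficient_n", cells = cells
    ))
  }

  # degenerate (essentially constant) data: limiting p-value instead of error
  p_value <- tryCatch(
    t.test(e_da_norm, e_d_norm, var.equal = equal_variance)$p.value,
    error = function(e) {
      if (isTRUE(all.equal(mean(e_da_norm), mean(e_d_norm)))) 1 else 0
    }
  )
  positive <- is.finite(p_value) && p_value < alpha &&
    mean(e_da_norm) > mean(e_d_norm)

  new_fret_pair_result(pair_name, e_da_norm, e_d_norm, e_d_median,
                       p_value, positive, alpha, flag = NA_character_,
                       cells = cells)
}

new_fret_pair_result <- function(pair_name, e_da_norm, e_d_norm, e_d_median,
                                 p_value, positive, alpha, flag, cells) {
  summaries <- list(
    DA = if (length(e_da_norm) >= 4) box_whisker_summary(e_da_norm) else NULL,
    D = if (length(e_d_norm) >= 4) box_whisker_summary(e_d_norm) else NULL
  )
  structure(
    list(
      pair_name = pair_name,
      efficiencies_DA_pct = e_da_norm,
      efficiencies_D_pct = e_d_norm,
      E_D_median = e_d_median,
      n_DA = length(e_da_norm),
      n_D = length(e_d_norm),
      p_value = p_value,
      positive = positive,
      alpha = alpha,
      flag = flag,
      summary = summaries,
      cells = cells
    ),
    class = "fret_pair_result"
  )
}

#' @export
print.fret_pair_result <- function(x, ...) {
  cat(sprintf("<fret_pair_result> %s\n", x$pair_name))
  cat(sprintf("  mean FRET efficiency%%: DA %.2f (n = %d), D %.2f (n = %d)\n",
              mean(x$efficiencies_DA_pct), x$n_DA,
              mean(x$efficiencies_D_pct), x$n_D))
  cat(sprintf("  donor-only median used for normalization: %.3f\n", x$E_D_median))
  cat(sprintf("  two-tailed Student t-test p = %.3g (alpha %.3g) -> %s\n",
              x$p_value, x$alpha,
              if (isTRUE(x$positive)) "POSITIVE FRET pair" else "negative"))
  if (!is.na(x$flag)) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' Quantify an acceptor-photobleaching FRET image set
#'
#' Runs the full donor de-quenching pipeline on a [simulate_fret_image_set()]
#' result (or a set read back from disk with [read_fret_image_set()]):
#' spot detection on the pre-bleach donor image, ROI mean measurement on both
#' donor phases at the detected center, per-phase background correction using
#' the untagged (`bg`) cells, per-cell percentage increase, normalization to
#' the donor-only median, and the positive/negative pair call.
#'
#' The background value for each phase is the mean of center-ROI means across
#' all `bg`-class cells (pooled per phase). Cells whose spot cannot be
#' detected or whose corrected pre-bleach intensity is not positive are
#' excluded and recorded with a reason in the `cells` table.
#'
#' @param image_set A `fret_image_set`.
#' @param roi_half_width ROI box half-size in pixels (box is
#'   `(2h + 1) x (2h + 1)`).
#' @param alpha Significance level for the pair call.
#' @param normalization `"subtract"` (default) or `"divide"`; see
#'   [normalize_to_donor_median()].
#' @param equal_variance Student (`TRUE`) or Welch (`FALSE`) t-test.
#' @param pair_name Label for the result; defaults to the fixture efficiency.
#' @return A `fret_pair_result` whose `cells` field is a tibble with one row
#'   per cell: raw and corrected ROI means, per-cell `e_pct`, normalized
#'   `e_norm_pct`, `included` and `exclude_reason`.
#' @export
#' @examples
#' set <- simulate_fret_image_set(sim_config(n_cells_DA = 6, n_cells_D = 6,
#'                                           n_cells_bg = 4, seed = 1))
#' quantify_image_set(set)
quantify_image_set <- function(image_set, roi_half_width = 2, alpha = 0.01,
                               normalization = c("subtract", "divide"),
                               equal_variance = TRUE, pair_name = NULL) {
  if (!inherits(image_set, "fret_image_set")) {
    abort("`image_set` must be a fret_image_set.")
  }
  normalization <- match.arg(normalization)
  manifest <- image_set$manifest
  for (cls in c("DA", "D", "bg")) {
    if (!any(manifest$class == cls)) {
      msg <- if (cls == "D") {
        "donor-only sample required: image set contains no 'D'-class cells."
      } else {
        sprintf("image set contains no '%s'-class cells.", cls)
      }
      abort(msg)
    }
  }
  pair_name <- pair_name %||%
    sprintf("sim_e%.3g", image_set$config$apparent_efficiency_pct)

  measurements <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    cell <- manifest[i, ]
    imgs <- image_set$images[[cell$cell_id]]
    if (cell$class == "bg") {
      # untagged cell: the whole frame is cytoplasm, so pool every pixel
      # (equivalent to averaging all ROIs tiling the image, and far less
      # noisy than a single box)
      return(tibble(
        cell_id = cell$cell_id, class = cell$class,
        roi_row = NA_real_, roi_col = NA_real_,
        fl_pre = mean(imgs$donor_pre),
        fl_post = mean(imgs$donor_post),
        spot_found = TRUE
      ))
    }
    spots <- detect_spots(imgs$donor_pre)
    if (nrow(spots) == 0L) {
      return(tibble(
        cell_id = cell$cell_id, class = cell$class,
        roi_row = NA_real_, roi_col = NA_real_,
        fl_pre = NA_real_, fl_post = NA_real_, spot_found = FALSE
      ))
    }
    r <- spots$row[1]
    c <- spots$col[1]
    tibble(
      cell_id = cell$cell_id, class = cell$class,
      roi_row = as.numeric(r), roi_col = as.numeric(c),
      fl_pre = measure_roi_mean(imgs$donor_pre, r, c, roi_half_width, cell$cell_id),
      fl_post = measure_roi_mean(imgs$donor_post, r, c, roi_half_width, cell$cell_id),
      spot_found = TRUE
    )
  })

  quantify_measurements(measurements, alpha = alpha,
                        normalization = normalization,
                        equal_variance = equal_variance,
                        pair_name = pair_name)
}

#' Quantify a pre-measured FRET intensity table
#'
#' Runs the background-correction / percentage-increase / donor-median
#' normalization / t-test pipeline on already-measured ROI means, e.g. a
#' table exported from an image-analysis tool. Rows of class `bg` provide the
#' per-phase background (mean over their `fl_pre` and `fl_post`).
#'
#' @param measurements Tibble with columns `cell_id`, `class`
#'   (`"DA"`/`"D"`/`"bg"`), `fl_pre`, `fl_post`.
#' @inheritParams quantify_image_set
#' @return A `fret_pair_result`.
#' @export
quantify_intensity_table <- function(measurements, alpha = 0.01,
                                     normalization = c("subtract", "divide"),
                                     equal_variance = TRUE,
                                     pair_name = "pair") {
  normalization <- match.arg(normalization)
  required <- c("cell_id", "class", "fl_pre", "fl_post")
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0) {
    abort(sprintf("measurement table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(measurements$class), c("DA", "D", "bg"))
  if (length(bad) > 0) {
    abort(sprintf("unknown class label(s) %s; allowed values are DA, D, bg.",
                  paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  measurements$spot_found <- TRUE
  quantify_measurements(as_tibble(measurements), alpha = alpha,
                        normalization = normalization,
                        equal_variance = equal_variance, pair_name = pair_name)
}

# Shared tail of the pipeline: background pooling, Eq-style corrections,
# donor-median normalization and the pair call.
quantify_measurements <- function(measurements, alpha, normalization,
                                  equal_variance, pair_name) {
  for (cls in c("DA", "D", "bg")) {
    if (!any(measurements$class == cls)) {
      msg <- if (cls == "D") {
        "donor-only sample required: no 'D'-class measurements."
      } else {
        sprintf("no '%s'-class measurements.", cls)
      }
      abort(msg)
    }
  }

  bg_rows <- measurements$class == "bg"
  fl_bg_pre <- mean(measurements$fl_pre[bg_rows], na.rm = TRUE)
  fl_bg_post <- mean(measurements$fl_post[bg_rows], na.rm = TRUE)

  cells <- dplyr::mutate(
    measurements,
    fl_bg_pre = fl_bg_pre,
    fl_bg_post = fl_bg_post,
    fl_cor_pre = .data$fl_pre - fl_bg_pre,
    fl_cor_post = .data$fl_post - fl_bg_post
  )
  cells <- dplyr::mutate(
    cells,
    exclude_reason = dplyr::case_when(
      .data$class == "bg" ~ "background sample",
      !.data$spot_found ~ "no spot detected",
      .data$fl_cor_pre <= 0 ~ "non-positive corrected pre-bleach intensity",
      TRUE ~ NA_character_
    ),
    included = is.na(.data$exclude_reason),
    e_pct = ifelse(.data$included,
                   100 * (.data$fl_cor_post - .data$fl_cor_pre) / .data$fl_cor_pre,
                   NA_real_)
  )

  excluded <- dplyr::filter(cells, !.data$included, .data$class != "bg")
  if (nrow(excluded) > 0) {
    inform(sprintf(
      "Excluded %d cell(s): %s.",
      nrow(excluded),
      paste(sprintf("%s (%s)", excluded$cell_id, excluded$exclude_reason),
            collapse = "; ")
    ))
  }

  e_da <- cells$e_pct[cells$included & cells$class == "DA"]
  e_d <- cells$e_pct[cells$included & cells$class == "D"]
  norm <- normalize_to_donor_median(e_da, e_d, method = normalization)

  cells$e_norm_pct <- NA_real_
  if (normalization == "subtract") {
    cells$e_norm_pct <- ifelse(cells$included, cells$e_pct - norm$e_d_median, NA_real_)
  } else {
    cells$e_norm_pct <- ifelse(cells$included, cells$e_pct / norm$e_d_median, NA_real_)
  }

  classify_fret_pair(norm$e_da_norm, norm$e_d_norm, alpha = alpha,
                     equal_variance = equal_variance, pair_name = pair_name,
                     e_d_median = norm$e_d_median, cells = cells)
}
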
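#' Detect diffraction-limited spots in a 2D intensity image
#'
#' Band-pass smooths the image (difference of Gaussians sized for a
#' diffraction-limited spot), then keeps local maxima exceeding
#' `background median + threshold_sd * robust SD` (median/MAD of the smoothed
#' image), non-maximum-suppressed so no two detections fall within
#' `min_separation_px` of each other.
#'
#' @param image Numeric matrix.
#' @param min_separation_px Minimum center-to-center distance between
#'   detections, pixels.
#' @param threshold_sd Detection threshold in robust standard deviations above
#'   the smoothed-image median.
#' @param smooth_sigma_px Gaussian sigma of the matched (narrow) filter; the
#'   wide background filter uses `4 * smooth_sigma_px`.
#' @return A tibble with columns `row`, `col` (1-based pixel coordinates of
#'   the peak) and `peak_value` (smoothed band-pass amplitude), sorted by
#'   descending `peak_value`. Zero rows on blank images.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[16, 20] <- 100
#' detect_spots(img)
detect_spots <- function(image, min_separation_px = 5, threshold_sd = 5,
                         smooth_sigma_px = 1.3) {
  assert_matrix_image(image)
  assert_number(min_separation_px, "min_separation_px", lower = 1)
  assert_number(threshold_sd, "threshold_sd", lower = 0)

  narrow <- gaussian_blur(image, smooth_sigma_px)
  wide <- gaussian_blur(image, 4 * smooth_sigma_px)
  bp <- narrow - wide

  bg <- median(bp)
  robust_sd <- mad(bp)
  if (robust_sd == 0) {
    # flat image (e.g. noiseless background): fall back to any positive excess
    robust_sd <- .Machine$double.eps
  }
  threshold <- bg + threshold_sd * robust_sd

  peaks <- local_maxima(bp, radius = ceiling(min_separation_px))
  keep <- peaks[bp[peaks] > threshold]
  if (length(keep) == 0L) {
    return(tibble(row = integer(), col = integer(), peak_value = numeric()))
  }

  nr <- nrow(bp)
  cand <- tibble(
    row = ((keep - 1L) %% nr) + 1L,
    col = ((keep - 1L) %/% nr) + 1L,
    peak_value = bp[keep]
  )
  cand <- dplyr::arrange(cand, dplyr::desc(.data$peak_value))

  # greedy non-maximum suppression at min_separation_px
  sel <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!sel[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1L):nrow(cand)
      d2 <- (cand$row[j] - cand$row[i])^2 + (cand$col[j] - cand$col[i])^2
      sel[j][d2 < min_separation_px^2] <- FALSE
    }
  }
  cand[sel, ]
}

#' Mean intensity in a square ROI around a spot
#'
#' Arithmetic mean of the `(2 h + 1) x (2 h + 1)` pixel box centered on
#' (`row`, `col`), the ROI convention used for SPB spot quantification.
#'
#' @param image Numeric matrix.
#' @param row,col Center pixel (1-based). Non-integer centers are rounded to
#'   the nearest pixel.
#' @param half_width_px Box half-size `h >= 1`.
#' @param cell_id Optional label used in the out-of-bounds error message.
#' @return Mean pixel value in the box.
#' @export
measure_roi_mean <- function(image, row, col, half_width_px = 2, cell_id = NULL) {
  assert_matrix_image(image)
  assert_number(half_width_px, "half_width_px", lower = 1, integerish = TRUE)
  r <- round(row)
  c <- round(col)
  h <- as.integer(half_width_px)
  if (r - h < 1 || r + h > nrow(image) || c - h < 1 || c + h > ncol(image)) {
    where <- if (is.null(cell_id)) "" else sprintf(" (cell %s)", cell_id)
    abort(sprintf(
      "ROI box [%d:%d, %d:%d] falls outside the %dx%d image%s.",
      r - h, r + h, c - h, c + h, nrow(image), ncol(image), where
    ))
  }
  mean(image[(r - h):(r + h), (c - h):(c + h)])
}

# Separable Gaussian blur with replicate-edge padding. Kernel weights are
# pixel-integrated (CDF differences) and truncated at 4 sigma.
gaussian_blur <- function(image, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  w <- pnorm(x + 0.5, sd = sigma) - pnorm(x - 0.5, sd = sigma)
  w <- w / sum(w)
  smoothed <- apply(image, 2, convolve_replicate, w = w, r = r)
  t(apply(t(smoothed), 2, convolve_replicate, w = w, r = r))
}

convolve_replicate <- function(v, w, r) {
  n <- length(v)
  padded <- c(rep(v[1], r), v, rep(v[n], r))
  out <- stats::filter(padded, w, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

# Linear indices of strict-or-tied local maxima within a square window of the
# given radius (a pixel must equal the window maximum).
local_maxima <- function(image, radius) {
  nr <- nrow(image)
  nc <- ncol(image)
  winmax <- image
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      shifted <- shift_matrix(image, dr, dc)
      winmax <- pmax(winmax, shifted)
    }
  }
  which(image >= winmax)
}

shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
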
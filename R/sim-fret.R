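#' Simulate an acceptor-photobleaching FRET image set
#'
#' Generates, for every simulated cell, the four single-plane images of the
#' acceptor-photobleaching protocol in acquisition order: acceptor pre-bleach,
#' donor pre-bleach, acceptor post-bleach, donor post-bleach. Three sample
#' classes are produced: `DA` (donor + acceptor pair), `D` (donor only) and
#' `bg` (untagged, background only).
#'
#' Photophysics: with quench factor `q = e / (100 + e)` (from the configured
#' apparent efficiency `e`), pairing fraction `p` and bleach completeness
#' `b`, the expected donor spot amplitude is `A (1 - q p)` before and
#' `A (1 - q p (1 - b)) (1 - d)` after the bleach pulse, where `d` is the
#' per-exposure acquisition bleaching. The acceptor spot goes from `A_a` to
#' `A_a (1 - b)`. Each pixel's expected photon count (spot + cytoplasmic
#' background) is Poisson-sampled, then camera offset and Gaussian read noise
#' are added; with `noise = FALSE` the expected values are returned directly.
#' Spots are pixel-integrated isotropic Gaussians, one per cell, jittered
#' around the image center.
#'
#' @param config A [sim_config()].
#' @return An object of class `fret_image_set`: a list with
#'   * `images`: named list (by cell id) of lists of four matrices
#'     (`acceptor_pre`, `donor_pre`, `acceptor_post`, `donor_post`);
#'   * `manifest`: tibble with one row per cell — `cell_id`, `class`
#'     (`DA`/`D`/`bg`), ground-truth spot center (`spot_row`, `spot_col`,
#'     1-based pixel coordinates), expected donor amplitudes pre/post, and the
#'     configured truth fields;
#'   * `config`: the input configuration.
#' @seealso [quantify_image_set()] to run the analysis pipeline on the result,
#'   [write_fret_image_set()] to write TIFFs + manifest to disk.
#' @export
#' @examples
#' set <- simulate_fret_image_set(sim_config(n_cells_DA = 4, n_cells_D = 4,
#'                                           n_cells_bg = 2, seed = 1))
#' set$manifest
simulate_fret_image_set <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  set.seed(config$seed)

  q <- quench_factor(config$apparent_efficiency_pct)
  p <- config$pairing_fraction
  b <- config$bleach_efficiency
  d <- config$acquisition_bleach_per_frame

  classes <- c(rep("DA", config$n_cells_DA),
               rep("D", config$n_cells_D),
               rep("bg", config$n_cells_bg))
  n <- length(classes)
  cell_ids <- sprintf("cell_%03d", seq_len(n))

  nr <- config$image_shape_px[1]
  nc <- config$image_shape_px[2]
  # keep the jittered spot well inside the frame (ROI margin)
  jitter_max <- 3
  centers_r <- (nr + 1) / 2 + runif(n, -jitter_max, jitter_max)
  centers_c <- (nc + 1) / 2 + runif(n, -jitter_max, jitter_max)

  donor_pre_amp <- ifelse(classes == "DA", config$donor_amplitude * (1 - q * p),
                   ifelse(classes == "D", config$donor_amplitude, 0))
  donor_post_amp <- ifelse(classes == "DA",
                           config$donor_amplitude * (1 - q * p * (1 - b)) * (1 - d),
                    ifelse(classes == "D", config$donor_amplitude * (1 - d), 0))
  acceptor_pre_amp <- ifelse(classes == "DA", config$acceptor_amplitude, 0)
  acceptor_post_amp <- acceptor_pre_amp * (1 - b)

  images <- vector("list", n)
  names(images) <- cell_ids
  for (i in seq_len(n)) {
    images[[i]] <- list(
      acceptor_pre = render_cell_image(acceptor_pre_amp[i], centers_r[i], centers_c[i], config),
      donor_pre = render_cell_image(donor_pre_amp[i], centers_r[i], centers_c[i], config),
      acceptor_post = render_cell_image(acceptor_post_amp[i], centers_r[i], centers_c[i], config),
      donor_post = render_cell_image(donor_post_amp[i], centers_r[i], centers_c[i], config)
    )
  }

  manifest <- tibble(
    cell_id = cell_ids,
    class = classes,
    spot_row = centers_r,
    spot_col = centers_c,
    donor_amp_pre = donor_pre_amp,
    donor_amp_post = donor_post_amp,
    apparent_efficiency_pct = config$apparent_efficiency_pct,
    pairing_fraction = p,
    bleach_efficiency = b
  )

  structure(
    list(images = images, manifest = manifest, config = config),
    class = "fret_image_set"
  )
}

#' @export
print.fret_image_set <- function(x, ...) {
  tab <- table(x$manifest$class)
  cat(sprintf(
    "<fret_image_set> %d cells (%s), %dx%d px, 4 pages per cell\n",
    nrow(x$manifest),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    x$config$image_shape_px[1], x$config$image_shape_px[2]
  ))
  invisible(x)
}

# Expected pixel image for one cell: pixel-integrated Gaussian spot of total
# expected photon count `amplitude` centered at (row, col), on a flat
# cytoplasmic background; then shot/read noise and camera offset.
render_cell_image <- function(amplitude, row, col, config) {
  expected <- gaussian_spot_image(amplitude, row, col,
                                  config$image_shape_px, config$psf_sigma_px) +
    config$cyto_background
  if (config$noise) {
    counts <- matrix(
      rpois(length(expected), lambda = expected),
      nrow = nrow(expected)
    )
    counts + config$camera_offset +
      matrix(rnorm(length(expected), sd = config$read_noise_sd), nrow = nrow(expected))
  } else {
    expected + config$camera_offset
  }
}

# Pixel-integrated isotropic Gaussian: pixel (i, j) covers
# [i - 0.5, i + 0.5] x [j - 0.5, j + 0.5], so its expected share of the total
# photon count factorizes into two normal-CDF differences.
gaussian_spot_image <- function(amplitude, row, col, shape, sigma) {
  if (amplitude == 0) {
    return(matrix(0, nrow = shape[1], ncol = shape[2]))
  }
  r <- seq_len(shape[1])
  c <- seq_len(shape[2])
  wr <- pnorm((r + 0.5 - row) / sigma) - pnorm((r - 0.5 - row) / sigma)
  wc <- pnorm((c + 0.5 - col) / sigma) - pnorm((c - 0.5 - col) / sigma)
  amplitude * outer(wr, wc)
}
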
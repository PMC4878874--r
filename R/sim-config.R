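#' Configuration for the synthetic acceptor-photobleaching FRET image generator
#'
#' Assembles and validates the full ground-truth parameterization for
#' [simulate_fret_image_set()]. The generator is parameterized by the
#' *apparent* FRET efficiency — the percentage increase in background-corrected
#' donor signal after complete acceptor photobleaching — because that is the
#' quantity the acceptor-photobleaching assay reports. Internally the apparent
#' efficiency `e` is converted to a donor quench factor `q = e / (100 + e)`, so
#' that with full pairing and complete bleaching the noiseless pipeline output
#' equals `e` exactly.
#'
#' @param apparent_efficiency_pct Target percentage donor de-quenching for
#'   donor+acceptor (DA) cells, in percent. Ground truth for recovery tests.
#' @param n_cells_DA,n_cells_D,n_cells_bg Number of simulated cells in the
#'   donor+acceptor, donor-only and untagged (background) classes.
#' @param donor_amplitude Expected total unquenched donor photons per SPB spot.
#' @param acceptor_amplitude Expected total acceptor photons per spot.
#' @param bleach_efficiency Fraction of acceptor destroyed by the bleach pulse,
#'   in `[0, 1]`.
#' @param pairing_fraction Fraction of donor molecules within Förster distance
#'   of a functional acceptor, in `[0, 1]`.
#' @param psf_sigma_px Standard deviation of the isotropic Gaussian
#'   point-spread function, in pixels.
#' @param cyto_background Expected cytoplasmic background photons per pixel.
#' @param camera_offset Constant camera offset added to every pixel (ADU).
#' @param read_noise_sd Standard deviation of additive Gaussian read noise.
#' @param acquisition_bleach_per_frame Fractional donor loss per donor
#'   exposure; the post-bleach donor image is attenuated by this factor. The
#'   donor-only median normalization exists to correct exactly this effect.
#' @param image_shape_px Integer vector of length 2, image rows and columns.
#' @param pixel_size_um Pixel size in micrometers.
#' @param noise If `FALSE`, disable Poisson shot noise and read noise; images
#'   contain expected values only (used for closed-form validation).
#' @param seed Integer seed; identical config + seed gives identical images.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [fixture_config()] for the shipped named parameter sets.
#' @export
sim_config <- function(apparent_efficiency_pct = 14,
                       n_cells_DA = 40,
                       n_cells_D = 40,
                       n_cells_bg = 20,
                       donor_amplitude = 5000,
                       acceptor_amplitude = 3000,
                       bleach_efficiency = 1,
                       pairing_fraction = 1,
                       psf_sigma_px = 1.3,
                       cyto_background = 50,
                       camera_offset = 100,
                       read_noise_sd = 2,
                       acquisition_bleach_per_frame = 0.01,
                       image_shape_px = c(48L, 48L),
                       pixel_size_um = 0.1067,
                       noise = TRUE,
                       seed = 1L) {
  assert_number(apparent_efficiency_pct, "apparent_efficiency_pct", lower = 0)
  assert_number(n_cells_DA, "n_cells_DA", lower = 0, strict_lower = TRUE, integerish = TRUE)
  if (!is.numeric(n_cells_D) || length(n_cells_D) != 1L || n_cells_D < 1) {
    abort("donor-only sample required: `n_cells_D` must be >= 1.")
  }
  assert_number(n_cells_D, "n_cells_D", lower = 0, strict_lower = TRUE, integerish = TRUE)
  assert_number(n_cells_bg, "n_cells_bg", lower = 0, strict_lower = TRUE, integerish = TRUE)
  assert_number(donor_amplitude, "donor_amplitude", lower = 0, strict_lower = TRUE)
  assert_number(acceptor_amplitude, "acceptor_amplitude", lower = 0, strict_lower = TRUE)
  assert_fraction(bleach_efficiency, "bleach_efficiency")
  assert_fraction(pairing_fraction, "pairing_fraction")
  assert_number(psf_sigma_px, "psf_sigma_px", lower = 0, strict_lower = TRUE)
  assert_number(cyto_background, "cyto_background", lower = 0)
  assert_number(camera_offset, "camera_offset", lower = 0)
  assert_number(read_noise_sd, "read_noise_sd", lower = 0)
  assert_fraction(acquisition_bleach_per_frame, "acquisition_bleach_per_frame")
  if (length(image_shape_px) != 2L) {
    abort("`image_shape_px` must have length 2 (rows, cols).")
  }
  assert_number(image_shape_px[1], "image_shape_px[1]", lower = 1, integerish = TRUE)
  assert_number(image_shape_px[2], "image_shape_px[2]", lower = 1, integerish = TRUE)
  # A spot (4 sigma) plus a 5x5 ROI and a margin must fit in the frame.
  min_dim <- ceiling(4 * psf_sigma_px) + 11
  if (any(image_shape_px < min_dim)) {
    abort(sprintf(
      "`image_shape_px` too small to contain a spot plus ROI margin (need >= %d px per side).",
      min_dim
    ))
  }
  assert_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  assert_flag(noise, "noise")
  assert_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      apparent_efficiency_pct = apparent_efficiency_pct,
      n_cells_DA = as.integer(n_cells_DA),
      n_cells_D = as.integer(n_cells_D),
      n_cells_bg = as.integer(n_cells_bg),
      donor_amplitude = donor_amplitude,
      acceptor_amplitude = acceptor_amplitude,
      bleach_efficiency = bleach_efficiency,
      pairing_fraction = pairing_fraction,
      psf_sigma_px = psf_sigma_px,
      cyto_background = cyto_background,
      camera_offset = camera_offset,
      read_noise_sd = read_noise_sd,
      acquisition_bleach_per_frame = acquisition_bleach_per_frame,
      image_shape_px = as.integer(image_shape_px),
      pixel_size_um = pixel_size_um,
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Configuration for synthetic FRAP recovery traces
#'
#' Parameterizes [simulate_frap_trace()]. Recovery follows a single
#' exponential: after an instantaneous drop by `bleach_depth` at the bleach
#' frame, intensity recovers as
#' `I(t) = I_bleach + (I_plateau - I_bleach) * (1 - exp(-k t))`,
#' where the plateau `1 - immobile_fraction * bleach_depth` (relative to the
#' pre-bleach level) reflects the immobile pool. Ground-truth half-recovery
#' time is `ln(2) / off_rate_per_s`.
#'
#' @param off_rate_per_s Exponential recovery (exchange) rate `k`, per second.
#'   `0` means no recovery.
#' @param immobile_fraction Fraction of the bleached pool that never recovers,
#'   in `[0, 1]`.
#' @param bleach_depth Fraction of pre-bleach intensity removed by the bleach
#'   pulse, in `(0, 1]`.
#' @param pre_bleach_frames,post_bleach_frames Frame counts before and after
#'   the bleach event.
#' @param frame_interval_s Time between frames, seconds.
#' @param intensity_scale Pre-bleach plateau intensity in arbitrary units.
#' @param noise_sd Additive Gaussian noise sd, in units of `intensity_scale`
#'   (0.1 corresponds to a signal-to-noise ratio of 10).
#' @param seed Integer seed.
#'
#' @return An object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(off_rate_per_s = log(2) / 11,
                            immobile_fraction = 0.2,
                            bleach_depth = 0.8,
                            pre_bleach_frames = 10L,
                            post_bleach_frames = 90L,
                            frame_interval_s = 1,
                            intensity_scale = 1,
                            noise_sd = 0.1,
                            seed = 1L) {
  assert_number(off_rate_per_s, "off_rate_per_s", lower = 0)
  assert_fraction(immobile_fraction, "immobile_fraction")
  assert_number(bleach_depth, "bleach_depth", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(pre_bleach_frames, "pre_bleach_frames", lower = 2, integerish = TRUE)
  assert_number(post_bleach_frames, "post_bleach_frames", lower = 4, integerish = TRUE)
  assert_number(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  assert_number(intensity_scale, "intensity_scale", lower = 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      off_rate_per_s = off_rate_per_s,
      immobile_fraction = immobile_fraction,
      bleach_depth = bleach_depth,
      pre_bleach_frames = as.integer(pre_bleach_frames),
      post_bleach_frames = as.integer(post_bleach_frames),
      frame_interval_s = frame_interval_s,
      intensity_scale = intensity_scale,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      t_half_s = if (off_rate_per_s > 0) log(2) / off_rate_per_s else Inf
    ),
    class = "frap_sim_config"
  )
}

#' Configuration for synthetic spindle-length time-lapse traces
#'
#' Parameterizes [simulate_spindle_traces()]. Each simulated cell follows a
#' biphasic trajectory: a metaphase plateau at `metaphase_length_um`, linear
#' rapid elongation starting at a drawn onset time, an anaphase plateau at
#' `plateau_length_um`, and an abrupt collapse (spindle breakdown) at
#' `onset + duration`, with onset and duration drawn from normal
#' distributions. Breakdown is always strictly after onset: durations are
#' truncated below at `min_duration_min`.
#'
#' @param n_cells Number of traces.
#' @param onset_mean_min,onset_sd_min Anaphase-onset time distribution, minutes.
#' @param duration_mean_min,duration_sd_min Anaphase duration (onset to
#'   breakdown) distribution, minutes.
#' @param metaphase_length_um Pre-anaphase spindle length, micrometers.
#' @param plateau_length_um Fully elongated spindle length, micrometers.
#' @param elongation_rate_um_min Rapid-elongation rate, micrometers per minute.
#' @param collapsed_length_um Apparent length after breakdown.
#' @param sampling_interval_min Time between length measurements, minutes.
#' @param total_time_min Observation span, minutes.
#' @param length_noise_sd_um Gaussian measurement noise on length.
#' @param min_duration_min Lower truncation for drawn durations.
#' @param seed Integer seed.
#'
#' @return An object of class `spindle_sim_config`.
#' @export
spindle_sim_config <- function(n_cells = 30L,
                               onset_mean_min = 10,
                               onset_sd_min = 2,
                               duration_mean_min = 23,
                               duration_sd_min = 4,
                               metaphase_length_um = 1.5,
                               plateau_length_um = 8,
                               elongation_rate_um_min = 1,
                               collapsed_length_um = 0.5,
                               sampling_interval_min = 1,
                               total_time_min = 60,
                               length_noise_sd_um = 0.05,
                               min_duration_min = 2,
                               seed = 1L) {
  assert_number(n_cells, "n_cells", lower = 0, strict_lower = TRUE, integerish = TRUE)
  assert_number(onset_mean_min, "onset_mean_min", lower = 0)
  assert_number(onset_sd_min, "onset_sd_min", lower = 0)
  assert_number(duration_mean_min, "duration_mean_min", lower = 0, strict_lower = TRUE)
  assert_number(duration_sd_min, "duration_sd_min", lower = 0)
  assert_number(metaphase_length_um, "metaphase_length_um", lower = 0, strict_lower = TRUE)
  assert_number(plateau_length_um, "plateau_length_um",
                lower = metaphase_length_um, strict_lower = TRUE)
  assert_number(elongation_rate_um_min, "elongation_rate_um_min", lower = 0, strict_lower = TRUE)
  assert_number(collapsed_length_um, "collapsed_length_um",
                lower = 0, upper = metaphase_length_um)
  assert_number(sampling_interval_min, "sampling_interval_min", lower = 0, strict_lower = TRUE)
  assert_number(total_time_min, "total_time_min", lower = 0, strict_lower = TRUE)
  assert_number(length_noise_sd_um, "length_noise_sd_um", lower = 0)
  assert_number(min_duration_min, "min_duration_min", lower = 0, strict_lower = TRUE)
  assert_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      n_cells = as.integer(n_cells),
      onset_mean_min = onset_mean_min,
      onset_sd_min = onset_sd_min,
      duration_mean_min = duration_mean_min,
      duration_sd_min = duration_sd_min,
      metaphase_length_um = metaphase_length_um,
      plateau_length_um = plateau_length_um,
      elongation_rate_um_min = elongation_rate_um_min,
      collapsed_length_um = collapsed_length_um,
      sampling_interval_min = sampling_interval_min,
      total_time_min = total_time_min,
      length_noise_sd_um = length_noise_sd_um,
      min_duration_min = min_duration_min,
      seed = as.integer(seed)
    ),
    class = "spindle_sim_config"
  )
}

#' Shipped fixture configurations
#'
#' Named parameter sets whose ground truth is pinned to the headline
#' quantities of the assays the package models: the structural reference FRET
#' pair (14% apparent efficiency), the tandem donor-acceptor fusion that
#' defines the ceiling of the mTUR/EYFP pair (26%), a donor-only null, fast
#' (half-recovery 11 s) and 6-fold slower FRAP exchange at the SPB during
#' spindle misalignment, and a 23-minute mean anaphase duration for correctly
#' aligned spindles.
#'
#' @param name One of `"spc42_cnm67"`, `"tandem_bfa1"`, `"donor_only"`,
#'   `"kar9_misaligned_frap"`, `"spc72_misaligned_frap"`,
#'   `"spc72_aligned_spindle"`.
#' @param seed Integer seed stored in the returned config.
#' @param ... Overrides passed to the underlying config constructor.
#'
#' @return A `sim_config`, `frap_sim_config` or `spindle_sim_config`.
#' @export
#' @examples
#' fixture_config("tandem_bfa1", seed = 7)
fixture_config <- function(name, seed = 1L, ...) {
  fixtures <- list(
    spc42_cnm67 = list(fn = sim_config,
                       args = list(apparent_efficiency_pct = 14)),
    tandem_bfa1 = list(fn = sim_config,
                       args = list(apparent_efficiency_pct = 26,
                                   pairing_fraction = 1)),
    donor_only = list(fn = sim_config,
                      args = list(apparent_efficiency_pct = 0)),
    kar9_misaligned_frap = list(fn = frap_sim_config,
                                args = list(off_rate_per_s = log(2) / 11)),
    spc72_misaligned_frap = list(fn = frap_sim_config,
                                 args = list(off_rate_per_s = log(2) / 66,
                                             post_bleach_frames = 240L)),
    spc72_aligned_spindle = list(fn = spindle_sim_config,
                                 args = list(duration_mean_min = 23,
                                             duration_sd_min = 4))
  )
  if (!name %in% names(fixtures)) {
    abort(sprintf("Unknown fixture '%s'. Available: %s.", name,
                  paste(names(fixtures), collapse = ", ")))
  }
  fx <- fixtures[[name]]
  args <- modifyList(c(fx$args, list(seed = seed)), list(...))
  do.call(fx$fn, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> acceptor-photobleaching FRET image simulation\n")
  cat(sprintf("  apparent efficiency: %.3g%%  (quench factor q = %.5f)\n",
              x$apparent_efficiency_pct, quench_factor(x$apparent_efficiency_pct)))
  cat(sprintf("  cells DA/D/bg: %d/%d/%d  image: %dx%d px  noise: %s  seed: %d\n",
              x$n_cells_DA, x$n_cells_D, x$n_cells_bg,
              x$image_shape_px[1], x$image_shape_px[2],
              if (x$noise) "on" else "off", x$seed))
  invisible(x)
}

#' @export
print.frap_sim_config <- function(x, ...) {
  cat("<frap_sim_config> single-exponential FRAP recovery simulation\n")
  cat(sprintf("  k = %.4g /s (t-half %.3g s), immobile %.2f, depth %.2f, noise sd %.3g, seed %d\n",
              x$off_rate_per_s, x$t_half_s, x$immobile_fraction, x$bleach_depth,
              x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.spindle_sim_config <- function(x, ...) {
  cat("<spindle_sim_config> biphasic spindle-length trace simulation\n")
  cat(sprintf("  n = %d, onset N(%.3g, %.3g) min, duration N(%.3g, %.3g) min, dt %.3g min, seed %d\n",
              x$n_cells, x$onset_mean_min, x$onset_sd_min,
              x$duration_mean_min, x$duration_sd_min,
              x$sampling_interval_min, x$seed))
  invisible(x)
}

# Apparent efficiency (percent increase under complete bleaching) -> donor
# quench factor. Inverse of 100 * q / (1 - q).
quench_factor <- function(e_pct) e_pct / (100 + e_pct)
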
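#' Simulate a per-cell two-SPB intensity table
#'
#' Generates paired spindle-pole-body fluorescence intensities with a
#' configured mean asymmetry. Per cell, a baseline intensity is drawn
#' log-normally (cell-to-cell variation); one pole receives the baseline, the
#' other `asymmetry_ratio` times it, and both are multiplied by independent
#' log-normal measurement noise with coefficient of variation `noise_cv`.
#' The bright pole's identity is recorded as ground truth so downstream
#' strong/weak (SPB1/SPB2) classification can be validated.
#'
#' @param n_cells Number of cells.
#' @param asymmetry_ratio Mean bright/dim intensity ratio, `>= 1`.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise.
#' @param seed Integer seed.
#' @param baseline_intensity Median baseline intensity (arbitrary units).
#' @param cell_cv Cell-to-cell coefficient of variation of the baseline.
#' @return A tibble with columns `cell_id`, `spb` (`"a"`/`"b"`, acquisition
#'   order), `intensity`, and `true_label` (`"bright"`/`"dim"`). Exactly two
#'   rows per cell; all intensities positive.
#' @seealso [classify_spb_table()]
#' @export
#' @examples
#' simulate_spb_intensity_table(3, asymmetry_ratio = 3, noise_cv = 0.1, seed = 1)
simulate_spb_intensity_table <- function(n_cells, asymmetry_ratio = 1,
                                         noise_cv = 0.1, seed = 1L,
                                         baseline_intensity = 100,
                                         cell_cv = 0.3) {
  assert_number(n_cells, "n_cells", lower = 0, strict_lower = TRUE, integerish = TRUE)
  assert_number(asymmetry_ratio, "asymmetry_ratio", lower = 1)
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(baseline_intensity, "baseline_intensity", lower = 0, strict_lower = TRUE)
  assert_number(cell_cv, "cell_cv", lower = 0)
  assert_number(seed, "seed", integerish = TRUE)
  set.seed(seed)

  # log-normal with median = baseline and multiplicative noise with the
  # requested CV (sdlog = sqrt(log(1 + cv^2)))
  sdlog_cell <- sqrt(log(1 + cell_cv^2))
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  base <- baseline_intensity * exp(rnorm(n_cells, 0, sdlog_cell))
  # which acquisition slot ("a" or "b") carries the bright pole is random
  bright_is_a <- runif(n_cells) < 0.5

  purrr::map_dfr(seq_len(n_cells), function(i) {
    bright <- base[i] * asymmetry_ratio * exp(rnorm(1, 0, sdlog_noise))
    dim <- base[i] * exp(rnorm(1, 0, sdlog_noise))
    int <- if (bright_is_a[i]) c(bright, dim) else c(dim, bright)
    lab <- if (bright_is_a[i]) c("bright", "dim") else c("dim", "bright")
    tibble(
      cell_id = sprintf("cell_%03d", i),
      spb = c("a", "b"),
      intensity = int,
      true_label = lab
    )
  })
}
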
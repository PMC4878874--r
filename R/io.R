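#' Write a FRET image set to disk
#'
#' Writes one multi-page 16-bit TIFF per cell (page order matching the
#' acquisition protocol: acceptor pre-bleach, donor pre-bleach, acceptor
#' post-bleach, donor post-bleach), a CSV manifest with the per-cell ground
#' truth, and a YAML echo of the generating configuration. Intensities are
#' stored as `round(value)` 16-bit counts; the quantization step is the only
#' place the pipeline leaves floating point.
#'
#' @param image_set A `fret_image_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_fret_image_set()]
#' @export
write_fret_image_set <- function(image_set, dir) {
  if (!inherits(image_set, "fret_image_set")) {
    abort("`image_set` must be a fret_image_set.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  page_order <- c("acceptor_pre", "donor_pre", "acceptor_post", "donor_post")
  for (cell_id in names(image_set$images)) {
    pages <- image_set$images[[cell_id]][page_order]
    scaled <- purrr::map(pages, function(m) {
      m <- round(m)
      if (any(m < 0)) m[m < 0] <- 0
      if (any(m > 65535)) m[m > 65535] <- 65535
      m / 65535
    })
    tiff::writeTIFF(scaled, file.path(dir, paste0(cell_id, ".tif")),
                    bits.per.sample = 16L)
  }
  readr::write_csv(image_set$manifest, file.path(dir, "manifest.csv"))
  cfg <- unclass(image_set$config)
  cfg$page_order <- page_order
  cfg$tiff_scale <- 65535
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a FRET image set written by [write_fret_image_set()]
#'
#' @param dir Directory containing per-cell TIFFs, `manifest.csv` and
#'   `config.yaml`.
#' @return A `fret_image_set` with intensities back on the count scale
#'   (16-bit quantized).
#' @export
read_fret_image_set <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest.csv in '%s'.", dir))
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  bad <- setdiff(unique(manifest$class), c("DA", "D", "bg"))
  if (length(bad) > 0) {
    abort(sprintf("manifest contains unknown class label(s) %s; allowed values are DA, D, bg.",
                  paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  page_order <- cfg$page_order %||%
    c("acceptor_pre", "donor_pre", "acceptor_post", "donor_post")
  scale <- cfg$tiff_scale %||% 65535

  images <- purrr::map(manifest$cell_id, function(cell_id) {
    path <- file.path(dir, paste0(cell_id, ".tif"))
    if (!file.exists(path)) {
      abort(sprintf("missing TIFF for cell '%s' ('%s').", cell_id, path))
    }
    pages <- tryCatch(
      tiff::readTIFF(path, all = TRUE),
      error = function(e) {
        abort(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
      }
    )
    if (length(pages) != length(page_order)) {
      abort(sprintf("TIFF '%s' has %d page(s); expected %d (%s).",
                    path, length(pages), length(page_order),
                    paste(page_order, collapse = ", ")))
    }
    setNames(purrr::map(pages, ~ .x * scale), page_order)
  })
  names(images) <- manifest$cell_id

  config <- tryCatch(
    do.call(sim_config, cfg[intersect(names(cfg), names(formals(sim_config)))]),
    error = function(e) NULL
  )
  structure(list(images = images, manifest = manifest, config = config),
            class = "fret_image_set")
}

#' Read a pre-measured FRET intensity table
#'
#' CSV with columns `cell_id`, `class` (`DA`/`D`/`bg`), `fl_pre`, `fl_post`;
#' the format accepted by [quantify_intensity_table()].
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_fret_intensities <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("cell_id", "class", "fl_pre", "fl_post")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("'%s' lacks column(s): %s.", path,
                  paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$class), c("DA", "D", "bg"))
  if (length(bad) > 0) {
    abort(sprintf("'%s' contains unknown class label(s) %s; allowed values are DA, D, bg.",
                  path, paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  tab
}

#' Write FRET pair results to disk
#'
#' Emits the per-cell measurement CSV, a schema-versioned pair-level JSON
#' (sample sizes, donor-only median, p-value, positive/negative call, group
#' means) and a box-whisker summary CSV for the two groups.
#'
#' @param result A `fret_pair_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fret_results <- function(result, dir) {
  if (!inherits(result, "fret_pair_result")) {
    abort("`result` must be a fret_pair_result.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$cells)) {
    readr::write_csv(result$cells, file.path(dir, "cells.csv"))
  }
  jsonlite::write_json(
    list(
      schema_version = "1.0",
      pair_name = result$pair_name,
      n_DA = result$n_DA,
      n_D = result$n_D,
      E_D_median = result$E_D_median,
      mean_DA_pct = mean(result$efficiencies_DA_pct),
      mean_D_pct = mean(result$efficiencies_D_pct),
      p_value = result$p_value,
      alpha = result$alpha,
      positive = result$positive
    ),
    file.path(dir, "pair_result.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(tidy(result), file.path(dir, "box_whisker.csv"))
  invisible(dir)
}
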
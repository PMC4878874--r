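# Internal argument checks. All stop() with the offending name so callers can
# see which field of a config failed.

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be an integer (got %s).", name, x))
  }
  invisible(x)
}

assert_fraction <- function(x, name) assert_number(x, name, lower = 0, upper = 1)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

assert_matrix_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (2D intensity image).", name))
  }
  invisible(x)
}

# Derive independent per-stage seeds from one master seed, keeping results
# below .Machine$integer.max so they remain valid R seeds.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(fret = 101L, frap = 211L, spindle = 307L, spb = 401L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}
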
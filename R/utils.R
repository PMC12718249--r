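# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators do not
#' perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a parent seed; keeps results stable when
# cohorts are extended dyad by dyad.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Band-limited Gaussian noise via a sum of random-phase sinusoids
#'
#' Draws from the caller's RNG stream. The result has (approximately) unit
#' standard deviation and spectral support restricted to [f_lo, f_hi].
#' @noRd
band_limited_noise <- function(t, f_lo, f_hi, n_components = 24L) {
  f <- seq(f_lo, f_hi, length.out = n_components)
  a <- stats::rnorm(n_components)
  b <- stats::rnorm(n_components)
  x <- drop(cos(2 * pi * outer(t, f)) %*% a + sin(2 * pi * outer(t, f)) %*% b)
  x / sqrt(n_components)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in field '%s': %s", field, msg), call. = FALSE)
}

# Zero-phase 4th-order Butterworth band-pass (signal::filtfilt doubles the
# attenuation and cancels phase).
butter_bandpass <- function(x, rate, band) {
  if (band[1] <= 0 || band[2] >= rate / 2)
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist=%g) at rate %g Hz",
                 band[1], band[2], rate / 2, rate), call. = FALSE)
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

butter_lowpass <- function(x, rate, cutoff) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop(sprintf("cutoff %g Hz outside (0, Nyquist=%g)", cutoff, rate / 2), call. = FALSE)
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  # filter around the mean: avoids the zero-initial-state edge transient
  m <- mean(x)
  as.numeric(signal::filtfilt(bf, x - m)) + m
}
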
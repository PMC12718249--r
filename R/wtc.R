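# Morlet continuous wavelet transform and wavelet-transform coherence with
# the standard time/scale smoothing, summarised as one band-of-interest
# coherence value per dyad x region x chromophore.

#' Wavelet analysis parameters
#'
#' @param omega0 Morlet nondimensional frequency (default 6; must be >= 5 for
#'   the analytic approximation to be admissible).
#' @param dj scale resolution in octaves (default 1/12, i.e. 12 scales per
#'   octave).
#' @param s0 smallest scale (default 2 x the sampling interval; resolved when
#'   the transform runs).
#' @param max_period optional cap on the analysed period, seconds.
#' @param smooth_dj0 width of the boxcar scale smoother, octaves (default 0.6).
#' @return object of class \code{wavelet_spec}.
#' @export
wavelet_spec <- function(omega0 = 6, dj = 1 / 12, s0 = NULL,
                         max_period = NULL, smooth_dj0 = 0.6) {
  if (omega0 < 5) stop("omega0 must be >= 5 (admissibility)")
  structure(list(omega0 = omega0, dj = dj, s0 = s0, max_period = max_period,
                 smooth_dj0 = smooth_dj0),
            class = "wavelet_spec")
}

fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT on a geometric scale grid. The series is linearly detrended
#' and variance-normalised (coherence is scale-free; detrending stabilises
#' edge behaviour), zero-padded to the next power of two, and transformed
#' with the analytic Morlet wavelet. The cone of influence is the e-folding
#' boundary: at distance \eqn{d} from the nearer edge, periods above
#' \eqn{d \cdot ff/\sqrt{2}} are edge-contaminated.
#'
#' @param x numeric series (no NAs), length >= 32.
#' @param dt sampling interval, seconds (default 1).
#' @param spec a \code{\link{wavelet_spec}}.
#' @return object of class \code{morlet_cwt}: complex \code{wave} (scale x
#'   time), \code{scales}, \code{periods} (s), \code{coi} (s per time point),
#'   \code{dt}, \code{dj}, \code{n}.
#' @export
cwt_morlet <- function(x, dt = 1, spec = wavelet_spec()) {
  if (anyNA(x)) stop("NAs in input; handle gaps upstream")
  n <- length(x)
  if (n < 32) stop("series must have at least 32 samples")
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))
  sdx <- stats::sd(x)
  if (sdx > 0) x <- x / sdx
  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  s0 <- spec$s0 %||% (2 * dt)
  jmax <- floor(log2(n * dt / s0) / spec$dj)
  scales <- s0 * 2^(spec$dj * (0:jmax))
  ff <- fourier_factor(spec$omega0)
  if (!is.null(spec$max_period)) scales <- scales[scales * ff <= spec$max_period]
  norm <- sqrt(2 * pi * scales / dt) * pi^(-1 / 4)
  filt <- matrix(0, length(scales), npad)
  pos <- omega > 0
  for (j in seq_along(scales))
    filt[j, pos] <- norm[j] * exp(-0.5 * (scales[j] * omega[pos] - spec$omega0)^2)
  prod <- filt * matrix(xf, length(scales), npad, byrow = TRUE)
  wave <- t(stats::mvfft(t(prod), inverse = TRUE)) / npad
  wave <- wave[, seq_len(n), drop = FALSE]
  dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  structure(list(wave = wave, scales = scales, periods = ff * scales,
                 coi = ff * dist / sqrt(2), dt = dt, dj = spec$dj,
                 omega0 = spec$omega0, smooth_dj0 = spec$smooth_dj0, n = n),
            class = "morlet_cwt")
}

# Smoothing operator of the standard coherence formulation: Gaussian in time
# with width matched to each scale, boxcar across scales of width
# smooth_dj0/dj points (fractional endpoints).
smooth_time <- function(field, scales, dt) {
  n <- ncol(field)
  npad <- 2^ceiling(log2(n))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / npad
  F <- t(stats::mvfft(t(cbind(field, matrix(0, nrow(field), npad - n)))))
  for (j in seq_len(nrow(field)))
    F[j, ] <- F[j, ] * exp(-0.5 * (scales[j] / dt * omega)^2)
  out <- t(stats::mvfft(t(F), inverse = TRUE)) / npad
  out[, seq_len(n), drop = FALSE]
}

smooth_scale_matrix <- function(n_scales, dj, dj0) {
  w <- dj0 / dj / 2            # half-width in scale steps
  S <- matrix(0, n_scales, n_scales)
  for (j in seq_len(n_scales)) {
    lo <- j - w; hi <- j + w
    idx <- max(1, floor(lo)):min(n_scales, ceiling(hi))
    wt <- pmin(idx + 0.5, hi) - pmax(idx - 0.5, lo)
    wt <- pmax(wt, 0)
    S[j, idx] <- wt / sum(wt)
  }
  S
}

smooth_field <- function(field, cwt) {
  st <- smooth_time(field, cwt$scales, cwt$dt)
  S <- smooth_scale_matrix(length(cwt$scales), cwt$dj, cwt$smooth_dj0)
  S %*% st
}

#' Pre-smooth the normalised wavelet power of a transform
#'
#' Attaches the smoothed autospectrum \eqn{S(|W|^2/s)} to a
#' \code{morlet_cwt}, so repeated coherence computations against the same
#' series (as in the random-pairing control) do not recompute it.
#'
#' @param cwt a \code{morlet_cwt}.
#' @return the transform with element \code{spow} added.
#' @export
smooth_wavelet_power <- function(cwt) {
  stopifnot(inherits(cwt, "morlet_cwt"))
  if (is.null(cwt$spow))
    cwt$spow <- pmax(Re(smooth_field(abs(cwt$wave)^2 / cwt$scales, cwt)), 0)
  cwt
}

#' Wavelet-transform coherence between two series
#'
#' \deqn{R^2(t,s) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\,S(|W_y|^2/s)}}
#' with smoothing \eqn{S} in time (Gaussian matched to scale) and across
#' scales (boxcar). Captures in-phase and phase-lagged association; without
#' smoothing coherence is identically 1, so unsmoothed computation is
#' refused.
#'
#' @param x,y numeric series of equal length at the same rate, or
#'   \code{morlet_cwt} objects on identical grids (optionally pre-smoothed
#'   with \code{\link{smooth_wavelet_power}}).
#' @param dt sampling interval (ignored when transforms are supplied).
#' @param spec a \code{\link{wavelet_spec}}.
#' @param smooth must remain TRUE.
#' @return object of class \code{coherence_field}: \code{rsq} (scale x time,
#'   in [0,1]), \code{periods}, \code{coi}, \code{dt}.
#' @export
wavelet_coherence <- function(x, y, dt = 1, spec = wavelet_spec(),
                              smooth = TRUE) {
  if (!isTRUE(smooth))
    stop("unsmoothed wavelet coherence is identically 1; refusing")
  cx <- if (inherits(x, "morlet_cwt")) x else cwt_morlet(x, dt, spec)
  cy <- if (inherits(y, "morlet_cwt")) y else cwt_morlet(y, dt, spec)
  if (cx$n != cy$n || length(cx$scales) != length(cy$scales) ||
      max(abs(cx$scales - cy$scales)) > 1e-12)
    stop("the two series/transforms must share length and scale grid")
  cx <- smooth_wavelet_power(cx)
  cy <- smooth_wavelet_power(cy)
  wxy <- cx$wave * Conj(cy$wave) / cx$scales
  sxy <- smooth_field(wxy, cx)
  denom <- cx$spow * cy$spow
  rsq <- Mod(sxy)^2 / denom
  rsq[denom < 1e-300] <- NA_real_
  rsq <- pmin(pmax(rsq, 0), 1)   # clip floating-point overshoot
  structure(list(rsq = rsq, periods = cx$periods, coi = cx$coi, dt = cx$dt),
            class = "coherence_field")
}

#' @export
print.coherence_field <- function(x, ...) {
  cat(sprintf("coherence_field: %d scales (periods %.1f-%.1f s) x %d samples\n",
              nrow(x$rsq), min(x$periods), max(x$periods), ncol(x$rsq)))
  invisible(x)
}

#' Average coherence over the frequency band of interest
#'
#' Mean squared coherence over scales whose period lies in
#' \code{[1/foi[2], 1/foi[1]]} seconds and over all time points. The default
#' band 0.02-0.1 Hz corresponds to 10-50 s periods, chosen to sit below
#' respiratory (~0.2-0.3 Hz), cardiac (~1 Hz) and Mayer-wave (~0.1 Hz)
#' physiological noise. Points under the cone of influence are excluded by
#' default; \code{coi_policy = "include"} reproduces the convention of tools
#' that average the full plane.
#'
#' @param field a \code{coherence_field}.
#' @param foi Hz pair (default c(0.02, 0.1)).
#' @param coi_policy \code{"exclude"} (default) or \code{"include"}.
#' @return scalar mean coherence in [0, 1], with attributes \code{foi},
#'   \code{period_range}, \code{coi_policy}, \code{n_cells}.
#' @export
average_foi <- function(field, foi = c(0.02, 0.1),
                        coi_policy = c("exclude", "include")) {
  coi_policy <- match.arg(coi_policy)
  stopifnot(inherits(field, "coherence_field"))
  pr <- c(1 / foi[2], 1 / foi[1])
  rows <- which(field$periods >= pr[1] & field$periods <= pr[2])
  if (!length(rows)) stop("frequency band of interest is empty on the scale grid")
  sub <- field$rsq[rows, , drop = FALSE]
  if (coi_policy == "exclude") {
    mask <- outer(field$periods[rows], field$coi, `>`)
    sub[mask] <- NA_real_
  }
  structure(mean(sub, na.rm = TRUE), foi = foi, period_range = pr,
            coi_policy = coi_policy, n_cells = sum(is.finite(sub)))
}

#' Band-of-interest coherence for every dyad, region and chromophore
#'
#' Runs wavelet coherence between each dyad's mother and child region series
#' and averages over the frequency band of interest, yielding the four
#' coherence values per dyad (left/right dlPFC x HbO/HbR).
#'
#' @param region_series list: per dyad, \code{mother} and \code{child} region
#'   series as produced by \code{\link{aggregate_region}} or
#'   \code{\link{generate_region_series}}.
#' @param dt sampling interval (default 1 s).
#' @param foi Hz pair.
#' @param coi_policy passed to \code{\link{average_foi}}.
#' @param spec a \code{\link{wavelet_spec}}.
#' @param chromophores chromophores to summarise (default HbO and HbR).
#' @return data.frame: dyad_id, region, chromophore, coherence, foi_low,
#'   foi_high, coi_policy.
#' @export
dyad_coherence <- function(region_series, dt = 1, foi = c(0.02, 0.1),
                           coi_policy = "exclude", spec = wavelet_spec(),
                           chromophores = c("hbo", "hbr")) {
  rows <- list()
  for (id in names(region_series)) {
    pair <- region_series[[id]]
    regions <- intersect(names(pair$mother), names(pair$child))
    for (r in regions) {
      if (is.null(pair$mother[[r]]) || is.null(pair$child[[r]])) next
      for (ch in chromophores) {
        fld <- wavelet_coherence(pair$mother[[r]][[ch]], pair$child[[r]][[ch]],
                                 dt = dt, spec = spec)
        co <- average_foi(fld, foi, coi_policy)
        rows[[length(rows) + 1L]] <-
          data.frame(dyad_id = id, region = r, chromophore = ch,
                     coherence = as.numeric(co), foi_low = foi[1],
                     foi_high = foi[2], coi_policy = coi_policy)
      }
    }
  }
  do.call(rbind, rows)
}
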
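# fNIRS preprocessing: raw two-wavelength intensities -> quality-controlled,
# motion-corrected, region-aggregated HbO/HbR/HbT at 1 Hz.
#
# The stage order (od -> prune -> spline -> wavelet -> hemoglobin -> filter ->
# downsample -> aggregate) is enforced: each operation records itself in the
# object's stage log and refuses to run twice.

check_stage <- function(x, op, requires = NULL) {
  stages <- attr(x, "stages") %||% character()
  if (op %in% stages)
    stop(sprintf("stage '%s' already applied (stage log: %s)", op,
                 paste(stages, collapse = " -> ")), call. = FALSE)
  if (!is.null(requires) && !all(requires %in% stages))
    stop(sprintf("stage '%s' requires prior stage(s): %s", op,
                 paste(setdiff(requires, stages), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

log_stage <- function(x, op) {
  attr(x, "stages") <- c(attr(x, "stages") %||% character(), op)
  x
}

#' Convert raw intensities to optical density
#'
#' \eqn{OD(t) = -\ln(I(t)/\bar I)} per channel and wavelength, with the
#' temporal mean as reference intensity, so the OD of the reference level is
#' zero by construction.
#'
#' @param rec an \code{intensity_recording} with strictly positive samples.
#' @return object of class \code{od_recording}: \code{od} (channel x
#'   wavelength x time), \code{reference} (channel x wavelength), plus the
#'   carried metadata.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "intensity_recording"))
  d <- dim(rec$intensity)
  bad <- which(apply(rec$intensity <= 0, 1, any))
  if (length(bad))
    stop(sprintf("nonpositive intensity in channel(s): %s",
                 paste(bad, collapse = ", ")))
  ref <- apply(rec$intensity, c(1, 2), mean)
  od <- -log(rec$intensity / as.vector(ref))   # ref recycles over time (3rd dim)
  out <- structure(list(od = od, reference = ref, rate = rec$rate,
                        time = rec$time, channels = rec$channels,
                        wavelengths = rec$wavelengths, role = rec$role,
                        person_id = rec$person_id, dyad_id = rec$dyad_id),
                   class = "od_recording")
  log_stage(out, "od")
}

#' @export
print.od_recording <- function(x, ...) {
  d <- dim(x$od)
  cat(sprintf("od_recording: %d channels x %d wavelengths x %d samples at %g Hz\n",
              d[1], d[2], d[3], x$rate))
  cat("  stages:", paste(attr(x, "stages"), collapse = " -> "), "\n")
  invisible(x)
}

#' Automated channel pruning
#'
#' Flags channels whose raw-intensity coefficient of variation exceeds
#' \code{cv_threshold} percent or whose flatline fraction (consecutive
#' near-identical samples) exceeds \code{flat_threshold}. A region with fewer
#' than 2 usable channels is invalid for that person, and a dyad with any
#' invalid region is excluded from the neural analyses.
#'
#' @param od an \code{od_recording} spanning at least 30 s.
#' @param cv_threshold percent (default 15).
#' @param flat_threshold proportion (default 0.05).
#' @return object of class \code{channel_quality}: data.frame with channel,
#'   region, cv_pct, flatline_fraction, usable, reason; attribute
#'   \code{region_valid} (named logical).
#' @export
prune_channels <- function(od, cv_threshold = 15, flat_threshold = 0.05) {
  stopifnot(inherits(od, "od_recording"))
  d <- dim(od$od)
  if (d[3] / od$rate < 30) stop("need at least 30 s of data")
  cv <- numeric(d[1]); flat <- numeric(d[1])
  for (ch in seq_len(d[1])) {
    cvw <- flw <- numeric(d[2])
    for (wl in seq_len(d[2])) {
      I <- od$reference[ch, wl] * exp(-od$od[ch, wl, ])
      cvw[wl] <- 100 * stats::sd(I) / mean(I)
      tol <- 1e-10 * max(abs(I), 1e-300)
      flw[wl] <- mean(abs(diff(I)) < tol)
    }
    cv[ch] <- max(cvw); flat[ch] <- max(flw)
  }
  reason <- rep("", d[1])
  reason[flat > flat_threshold] <- "flatline"
  reason[cv > cv_threshold] <- paste0(reason[cv > cv_threshold],
                                      ifelse(nzchar(reason[cv > cv_threshold]), "+", ""),
                                      "high_cv")
  usable <- !nzchar(reason)
  q <- data.frame(channel = od$channels$channel, region = od$channels$region,
                  cv_pct = cv, flatline_fraction = flat,
                  usable = usable, reason = reason)
  rv <- tapply(q$usable, q$region, sum) >= 2
  structure(q, region_valid = rv, class = c("channel_quality", "data.frame"))
}

# Smooth trend of a short segment: cubic smoothing spline when long enough,
# low-order polynomial otherwise.
segment_trend <- function(y) {
  n <- length(y)
  if (n >= 10) {
    fit <- stats::smooth.spline(seq_len(n), y,
                                df = min(n - 1, max(4, ceiling(n / 3))))
    stats::predict(fit, seq_len(n))$y
  } else {
    tt <- seq_len(n)
    stats::fitted(stats::lm(y ~ poly(tt, degree = min(3, n - 1))))
  }
}

#' Spline-based motion artifact correction
#'
#' Motion segments are flagged where the moving standard deviation (window
#' \code{detect_window} seconds) exceeds \code{detect_k} times its median.
#' Within each flagged segment the smooth trend (cubic spline) is subtracted
#' and the segment re-levelled to match the preceding clean level; data after
#' the segment is shifted so the series stays continuous, which removes step
#' baseline shifts.
#'
#' @param od an \code{od_recording}.
#' @param detect_window seconds (default 1).
#' @param detect_k multiplier on the median moving SD (default 5).
#' @return corrected \code{od_recording}; channels that are flagged in their
#'   entirety are recorded in attribute \code{unusable_channels} instead of
#'   corrected.
#' @export
spline_motion_correct <- function(od, detect_window = 1, detect_k = 5) {
  stopifnot(inherits(od, "od_recording"))
  check_stage(od, "spline", requires = "od")
  w <- max(3L, round(od$rate * detect_window))
  d <- dim(od$od)
  unusable <- integer()
  for (ch in seq_len(d[1])) for (wl in seq_len(d[2])) {
    x <- od$od[ch, wl, ]
    msd <- moving_sd(x, w)
    flags <- msd > detect_k * stats::median(msd)
    if (all(flags)) { unusable <- union(unusable, ch); next }
    if (!any(flags)) next
    od$od[ch, wl, ] <- correct_flagged_segments(x, flags, w)
  }
  attr(od, "unusable_channels") <- unusable
  log_stage(od, "spline")
}

moving_sd <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  half <- w %/% 2
  lo <- pmax(1L, seq_len(n) - half); hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo + 1L
  v <- (cs2[hi + 1L] - cs2[lo] - (cs[hi + 1L] - cs[lo])^2 / m) / pmax(m - 1L, 1L)
  sqrt(pmax(v, 0))
}

correct_flagged_segments <- function(x, flags, w) {
  n <- length(x)
  # dilate flags by a full window (covers spike decay tails), merge near runs
  f <- flags
  idx <- which(flags)
  for (k in seq(-w, w)) {
    sh <- idx + k
    f[sh[sh >= 1 & sh <= n]] <- TRUE
  }
  r <- rle(f)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- x
  offset <- 0
  # local low-order trend of clean data, evaluated at arbitrary positions;
  # quadratic when the window supports it (tracks slow oscillations across
  # the gap), linear or flat otherwise
  local_line <- function(pos, vals, at) {
    if (length(pos) < 3) return(rep(mean(vals), length(at)))
    p0 <- mean(pos)
    if (length(pos) >= 12) {
      cf <- stats::coef(stats::lm(vals ~ I(pos - p0) + I((pos - p0)^2)))
      cf[1] + cf[2] * (at - p0) + cf[3] * (at - p0)^2
    } else {
      cf <- stats::coef(stats::lm(vals ~ I(pos - p0)))
      cf[1] + cf[2] * (at - p0)
    }
  }
  for (j in seq_along(r$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    if (!r$values[j]) { out[i1:i2] <- x[i1:i2] + offset; next }
    seg <- x[i1:i2] + offset
    pre_idx <- which(!f[max(1, i1 - 4 * w):max(1, i1 - 1)]) + max(1, i1 - 4 * w) - 1L
    pre_idx <- pre_idx[pre_idx < i1]
    detr <- seg - segment_trend(seg)
    if (length(pre_idx) >= 3) {
      out[i1:i2] <- detr - mean(detr) + local_line(pre_idx, out[pre_idx], i1:i2)
    } else {
      out[i1:i2] <- detr - mean(detr) + stats::median(seg)
    }
    if (i2 < n) {
      # re-anchor subsequent data so its local trend continues the corrected
      # pre-artifact trend: removes step baseline shifts, leaves spikes alone
      post_idx <- which(!f[min(n, i2 + 1):min(n, i2 + 4 * w)]) + i2
      post_idx <- post_idx[post_idx <= n]
      if (length(post_idx) >= 3 && length(pre_idx) >= 3) {
        at <- (i1 + i2) / 2   # same point for both sides: clean signal cancels
        pre_pred <- local_line(pre_idx, out[pre_idx], at)
        post_pred <- local_line(post_idx, x[post_idx], at)
        offset <- pre_pred - post_pred
      }
    }
  }
  out
}

# ---- Periodised orthonormal Daubechies (4-tap) discrete wavelet transform --

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

dwt_step <- function(x) {
  f <- daub4_filters()
  n <- length(x)
  k <- seq_len(n / 2)
  pos <- function(m) ((2 * (k - 1) + m - 1) %% n) + 1
  a <- f$h[1] * x[pos(1)] + f$h[2] * x[pos(2)] + f$h[3] * x[pos(3)] + f$h[4] * x[pos(4)]
  d <- f$g[1] * x[pos(1)] + f$g[2] * x[pos(2)] + f$g[3] * x[pos(3)] + f$g[4] * x[pos(4)]
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  f <- daub4_filters()
  n <- 2 * length(a)
  x <- numeric(n)
  k <- seq_along(a)
  for (m in 1:4) {
    pos <- ((2 * (k - 1) + m - 1) %% n) + 1
    contrib <- f$h[m] * a + f$g[m] * d
    # accumulate with possible repeated positions (none here: stride 2, m<=4)
    x[pos] <- x[pos] + contrib
  }
  x
}

#' Periodised Daubechies-4 wavelet decomposition
#' @param x numeric vector whose length is a multiple of 2^levels.
#' @param levels decomposition depth.
#' @return list with approximation \code{a} and details \code{d} (list,
#'   finest first).
#' @export
dwt_periodic <- function(x, levels) {
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    a <- s$a; d[[j]] <- s$d
  }
  list(a = a, d = d)
}

#' Inverse of \code{\link{dwt_periodic}}
#' @param w list as returned by \code{dwt_periodic}.
#' @return reconstructed numeric vector.
#' @export
idwt_periodic <- function(w) {
  a <- w$a
  for (j in rev(seq_along(w$d))) a <- idwt_step(a, w$d[[j]])
  a
}

#' Wavelet-based motion artifact correction
#'
#' Decomposes each channel with a periodised Daubechies-4 discrete wavelet
#' transform (reflection-padded to a power of two) and zeroes detail
#' coefficients lying outside the quartiles by more than \code{iqr_k} times
#' the interquartile range, then reconstructs. Spike-like transients load on
#' large isolated detail coefficients and are attenuated; a Gaussian signal
#' loses almost nothing.
#'
#' @param od an \code{od_recording} with at least 64 samples.
#' @param iqr_k IQR multiplier (default 1.5).
#' @return corrected \code{od_recording}.
#' @export
wavelet_motion_correct <- function(od, iqr_k = 1.5) {
  stopifnot(inherits(od, "od_recording"))
  check_stage(od, "wavelet", requires = "od")
  d <- dim(od$od)
  if (d[3] < 64) {
    warning("series shorter than 64 samples; wavelet correction skipped")
    return(log_stage(od, "wavelet"))
  }
  for (ch in seq_len(d[1])) for (wl in seq_len(d[2]))
    od$od[ch, wl, ] <- wavelet_despike(od$od[ch, wl, ], iqr_k)
  log_stage(od, "wavelet")
}

wavelet_despike <- function(x, iqr_k) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  pad <- npad - n
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x   # reflection padding
  levels <- min(6L, floor(log2(npad)) - 3L)
  w <- dwt_periodic(xp, levels)
  for (j in seq_along(w$d)) {
    dj <- w$d[[j]]
    q <- stats::quantile(dj, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- dj < q[1] - iqr_k * iqr | dj > q[2] + iqr_k * iqr
    dj[out] <- 0
    w$d[[j]] <- dj
  }
  idwt_periodic(w)[seq_len(n)]
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law: per channel and sample the 2x2 system
#' \eqn{OD_\lambda = (\epsilon_{HbO,\lambda} \Delta HbO +
#' \epsilon_{HbR,\lambda} \Delta HbR) \, d \, DPF_\lambda} is solved for
#' \eqn{\Delta HbO, \Delta HbR}; \eqn{HbT = HbO + HbR}. Units micromolar.
#'
#' @param od an \code{od_recording}.
#' @param age participant age in years (sets the DPF); defaults by role.
#' @param dpf optional length-2 DPF override (760, 850 nm).
#' @param distance_cm optional source-detector distance override.
#' @return object of class \code{hemo_recording} with \code{hbo}, \code{hbr},
#'   \code{hbt} (channel x time, micromolar).
#' @export
od_to_hemoglobin <- function(od, age = NULL, dpf = NULL, distance_cm = NULL) {
  stopifnot(inherits(od, "od_recording"))
  check_stage(od, "hemoglobin", requires = "od")
  if (is.null(dpf)) {
    if (is.null(age)) age <- if (identical(od$role, "child")) 6 else 36
    dpf <- dpf_for_age(od$wavelengths, age)
  }
  d <- dim(od$od)
  nch <- d[1]
  hbo <- hbr <- matrix(NA_real_, nch, d[3])
  for (ch in seq_len(nch)) {
    dist <- distance_cm %||% od$channels$distance_cm[ch]
    A <- mbll_matrix(dist, dpf)
    if (abs(det(A)) < 1e-12)
      stop_config("extinction matrix", "singular; check wavelengths/DPF")
    conc <- solve(A, rbind(od$od[ch, 1, ], od$od[ch, 2, ])) * 1e6  # M -> uM
    hbo[ch, ] <- conc[1, ]; hbr[ch, ] <- conc[2, ]
  }
  out <- structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                        rate = od$rate, time = od$time, channels = od$channels,
                        role = od$role, person_id = od$person_id,
                        dyad_id = od$dyad_id),
                   class = "hemo_recording")
  attr(out, "stages") <- attr(od, "stages")
  log_stage(out, "hemoglobin")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("hemo_recording: %d channels x %d samples at %g Hz (uM)\n",
              nrow(x$hbo), ncol(x$hbo), x$rate))
  cat("  stages:", paste(attr(x, "stages"), collapse = " -> "), "\n")
  invisible(x)
}

#' Band-pass filter hemoglobin series
#'
#' Deliberately wide zero-phase default band (0.01-0.5 Hz): it removes drift
#' and cardiac pulsation while leaving the narrow frequency-band-of-interest
#' selection to the coherence averaging step.
#'
#' @param hemo a \code{hemo_recording}.
#' @param band Hz pair (default c(0.01, 0.5)).
#' @return filtered \code{hemo_recording} (HbT recomputed).
#' @export
bandpass_hemo <- function(hemo, band = c(0.01, 0.5)) {
  stopifnot(inherits(hemo, "hemo_recording"))
  check_stage(hemo, "filter", requires = "hemoglobin")
  for (ch in seq_len(nrow(hemo$hbo))) {
    hemo$hbo[ch, ] <- butter_bandpass(hemo$hbo[ch, ], hemo$rate, band)
    hemo$hbr[ch, ] <- butter_bandpass(hemo$hbr[ch, ], hemo$rate, band)
  }
  hemo$hbt <- hemo$hbo + hemo$hbr
  log_stage(hemo, "filter")
}

#' Downsample hemoglobin series
#'
#' Anti-alias low-pass at 0.4 x target rate, then cubic interpolation onto
#' the exact target grid (handles the non-integer 7.81 -> 1 Hz ratio).
#'
#' @param hemo a \code{hemo_recording}.
#' @param target output rate, Hz (default 1).
#' @return \code{hemo_recording} at the target rate.
#' @export
downsample_hemo <- function(hemo, target = 1) {
  stopifnot(inherits(hemo, "hemo_recording"))
  check_stage(hemo, "downsample", requires = "hemoglobin")
  if (target >= hemo$rate) stop("target rate must be below the input rate")
  grid <- seq(hemo$time[1], hemo$time[length(hemo$time)], by = 1 / target)
  resample <- function(m) {
    out <- matrix(NA_real_, nrow(m), length(grid))
    for (ch in seq_len(nrow(m))) {
      lp <- butter_lowpass(m[ch, ], hemo$rate, 0.4 * target)
      out[ch, ] <- stats::spline(hemo$time, lp, xout = grid)$y
    }
    out
  }
  hemo$hbo <- resample(hemo$hbo)
  hemo$hbr <- resample(hemo$hbr)
  hemo$hbt <- hemo$hbo + hemo$hbr
  hemo$time <- grid
  hemo$rate <- target
  log_stage(hemo, "downsample")
}

#' Aggregate channels into region series
#'
#' Mean over usable channels per region, separately for each chromophore.
#' A region with fewer than 2 usable channels is invalid.
#'
#' @param hemo a \code{hemo_recording}.
#' @param quality a \code{channel_quality} (default: all channels usable).
#' @return named list per region with elements \code{hbo}, \code{hbr},
#'   \code{hbt} (numeric series); invalid regions are \code{NULL} and named
#'   in attribute \code{invalid_regions}.
#' @export
aggregate_region <- function(hemo, quality = NULL) {
  stopifnot(inherits(hemo, "hemo_recording"))
  usable <- if (is.null(quality)) rep(TRUE, nrow(hemo$hbo)) else quality$usable
  regions <- unique(hemo$channels$region)
  out <- list(); invalid <- character()
  for (r in regions) {
    sel <- hemo$channels$region == r & usable
    if (sum(sel) < 2) { out[r] <- list(NULL); invalid <- c(invalid, r); next }
    out[[r]] <- list(hbo = colMeans(hemo$hbo[sel, , drop = FALSE]),
                     hbr = colMeans(hemo$hbr[sel, , drop = FALSE]),
                     hbt = colMeans(hemo$hbt[sel, , drop = FALSE]))
  }
  attr(out, "invalid_regions") <- invalid
  out
}

#' Channel accounting summary
#'
#' Bookkeeping of usable data: analyzed channels = usable dyads x 2
#' participants x channels per person; percentages against the enrolled
#' total.
#'
#' @param n_usable_dyads dyads that survived quality control.
#' @param n_enrolled_dyads dyads enrolled.
#' @param channels_per_person channels per participant (default 8).
#' @return list with \code{analyzed_channels}, \code{total_channels},
#'   \code{pct_usable}, \code{pct_excluded}, \code{n_excluded}.
#' @export
channel_accounting <- function(n_usable_dyads, n_enrolled_dyads,
                               channels_per_person = 8L) {
  analyzed <- as.integer(n_usable_dyads) * 2L * as.integer(channels_per_person)
  total <- as.integer(n_enrolled_dyads) * 2L * as.integer(channels_per_person)
  list(analyzed_channels = analyzed, total_channels = total,
       pct_usable = if (total > 0) 100 * analyzed / total else 0,
       pct_excluded = if (n_enrolled_dyads > 0)
         100 * (n_enrolled_dyads - n_usable_dyads) / n_enrolled_dyads else 0,
       n_excluded = n_enrolled_dyads - n_usable_dyads)
}

#' Full fNIRS preprocessing for one person
#'
#' Enforced order: OD conversion, channel pruning, spline motion correction,
#' wavelet motion correction, hemoglobin conversion, band-pass, downsample to
#' 1 Hz, region aggregation.
#'
#' @param rec an \code{intensity_recording}.
#' @param age participant age (DPF); defaults by role.
#' @param cv_threshold,flat_threshold passed to \code{\link{prune_channels}}.
#' @param band passed to \code{\link{bandpass_hemo}}.
#' @param target_rate output rate (default 1 Hz).
#' @return list with \code{region_series}, \code{quality}, \code{hemo},
#'   \code{usable} (logical: both regions valid).
#' @export
fnirs_preprocess <- function(rec, age = NULL, cv_threshold = 15,
                             flat_threshold = 0.05, band = c(0.01, 0.5),
                             target_rate = 1) {
  od <- intensity_to_od(rec)
  quality <- prune_channels(od, cv_threshold, flat_threshold)
  od <- spline_motion_correct(od)
  bad <- attr(od, "unusable_channels")
  if (length(bad)) quality$usable[quality$channel %in% bad] <- FALSE
  od <- wavelet_motion_correct(od)
  hemo <- od_to_hemoglobin(od, age = age)
  hemo <- bandpass_hemo(hemo, band)
  hemo <- downsample_hemo(hemo, target_rate)
  region_series <- aggregate_region(hemo, quality)
  list(region_series = region_series, quality = quality, hemo = hemo,
       usable = length(attr(region_series, "invalid_regions")) == 0)
}
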
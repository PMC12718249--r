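# Cardiac branch: interbeat intervals -> continuous RSA -> epochs.

#' Interbeat-interval series
#'
#' Holds strictly increasing beat times (seconds) and the implied interbeat
#' intervals (ms), each labelled as belonging to the resting baseline or the
#' stress task by the beat's ending time.
#'
#' @param beat_times numeric, strictly increasing, seconds.
#' @param baseline_duration seconds; beats ending at or before this time are
#'   labelled \code{"baseline"}, later beats \code{"task"}.
#' @param person_id,dyad_id,role identifiers; \code{role} is \code{"mother"}
#'   or \code{"child"}.
#' @return object of class \code{ibi_series} with fields \code{beat_times},
#'   \code{ibis} (ms), \code{segment}, \code{usable}, \code{reason}.
#' @export
ibi_series <- function(beat_times, baseline_duration = 0,
                       person_id = NA_character_, dyad_id = NA_character_,
                       role = c("mother", "child")) {
  role <- match.arg(role)
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) stop("need at least 2 beat times")
  ibis <- diff(beat_times) * 1000
  if (any(ibis <= 0)) stop("beat times must be strictly increasing")
  structure(list(beat_times = beat_times, ibis = ibis,
                 segment = ifelse(beat_times[-1] <= baseline_duration,
                                  "baseline", "task"),
                 baseline_duration = baseline_duration,
                 person_id = person_id, dyad_id = dyad_id, role = role,
                 usable = TRUE, reason = NULL),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("ibi_series: %d beats over %.1f s (%s, dyad %s)%s\n",
              length(x$ibis), diff(range(x$beat_times)), x$role, x$dyad_id,
              if (x$usable) "" else " [UNUSABLE]"))
  cat(sprintf("  IBI mean %.0f ms, range [%.0f, %.0f] ms\n",
              mean(x$ibis), min(x$ibis), max(x$ibis)))
  invisible(x)
}

#' Restrict an IBI series to one segment
#' @param ibi an \code{ibi_series}.
#' @param which \code{"baseline"} or \code{"task"}.
#' @return an \code{ibi_series} covering only the requested segment, with beat
#'   times re-referenced to the segment start.
#' @export
ibi_segment <- function(ibi, which = c("task", "baseline")) {
  which <- match.arg(which)
  keep <- ibi$segment == which
  if (sum(keep) < 2) stop(sprintf("segment '%s' has fewer than 2 beats", which))
  idx <- which(keep)
  bt <- ibi$beat_times[c(idx[1], idx + 1L)]
  t0 <- if (which == "task") ibi$baseline_duration else 0
  out <- ibi_series(bt - t0, baseline_duration = 0,
                    person_id = ibi$person_id, dyad_id = ibi$dyad_id,
                    role = ibi$role)
  out$segment <- rep(which, length(out$ibis))
  out
}

#' Automated interbeat-interval artifact correction
#'
#' Automated counterpart of manual beat editing: each interval is compared
#' with the running median of its 9 neighbours; intervals more than
#' \code{threshold_pct} below the median are merged with their successor
#' (a spuriously detected extra beat), intervals more than
#' \code{threshold_pct} above are split into \code{round(IBI/median)} equal
#' beats (missed beats). Total elapsed time is conserved exactly. If more
#' than 20\% of beats are flagged on the first pass the series is marked
#' unusable rather than corrected, mirroring the drop rule for dyads whose
#' recordings cannot be cleaned reliably.
#'
#' @param ibi an \code{ibi_series} with at least 10 beats.
#' @param threshold_pct proportional deviation that flags a beat (default 0.30).
#' @param max_flagged_frac fraction of flagged beats above which the series is
#'   marked unusable (default 0.20).
#' @return corrected \code{ibi_series}; check \code{$usable}.
#' @export
correct_ibi_artifacts <- function(ibi, threshold_pct = 0.30,
                                  max_flagged_frac = 0.20) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi$ibis) < 10) stop("need at least 10 beats")
  flag_frac <- {
    med <- stats::runmed(ibi$ibis, 9, endrule = "median")
    mean(ibi$ibis < (1 - threshold_pct) * med |
           ibi$ibis > (1 + threshold_pct) * med)
  }
  if (flag_frac > max_flagged_frac) {
    out <- ibi
    out$usable <- FALSE
    out$reason <- sprintf("%.0f%% of beats flagged (> %.0f%%): unusable",
                          100 * flag_frac, 100 * max_flagged_frac)
    return(out)
  }
  x <- ibi$ibis
  for (pass in 1:10) {
    med <- stats::runmed(x, min(9L, length(x) - (1 - length(x) %% 2)),
                         endrule = "median")
    lo <- x < (1 - threshold_pct) * med
    hi <- x > (1 + threshold_pct) * med
    if (!any(lo | hi)) break
    out <- vector("list", length(x))
    i <- 1L
    while (i <= length(x)) {
      if (lo[i] && i < length(x)) {
        out[[i]] <- x[i] + x[i + 1L]    # merge spurious beat with successor
        i <- i + 2L
      } else if (hi[i]) {
        k <- max(1L, round(x[i] / med[i]))
        out[[i]] <- rep(x[i] / k, k)    # split missed beats
        i <- i + 1L
      } else {
        out[[i]] <- x[i]
        i <- i + 1L
      }
    }
    x_new <- unlist(out)
    if (isTRUE(all.equal(x_new, x))) break
    x <- x_new
  }
  stopifnot(abs(sum(x) - sum(ibi$ibis)) < 1)  # elapsed time conserved < 1 ms
  res <- ibi_series(ibi$beat_times[1] + c(0, cumsum(x)) / 1000,
                    baseline_duration = ibi$baseline_duration,
                    person_id = ibi$person_id, dyad_id = ibi$dyad_id,
                    role = ibi$role)
  res$baseline_duration <- ibi$baseline_duration
  res$segment <- ifelse(res$beat_times[-1] <= ibi$baseline_duration,
                        "baseline", "task")
  res
}

#' Resample an IBI series onto a uniform grid
#'
#' Cubic interpolation of the interbeat interval (as a function of the beat's
#' ending time) sampled at a fixed rate, yielding the uniformly sampled heart
#' period series that band-pass filtering requires.
#'
#' @param ibi an \code{ibi_series}.
#' @param rate output sampling rate, Hz (default 4).
#' @return list with \code{time} (s), \code{values} (ms) and \code{rate}.
#' @export
ibi_to_uniform <- function(ibi, rate = 4) {
  stopifnot(inherits(ibi, "ibi_series"))
  tt <- ibi$beat_times[-1]
  if (diff(range(tt)) < 2 / rate) stop("series span shorter than 2 samples")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / rate)
  vals <- stats::spline(tt, ibi$ibis, xout = grid, method = "fmm")$y
  list(time = grid, values = vals, rate = rate)
}

#' Respiratory-band zero-phase filter for heart period series
#'
#' Isolates the respiratory frequency range in which vagally mediated heart
#' period variability (RSA) lives. Band defaults follow psychophysiology
#' convention: 0.12-0.40 Hz for adults, 0.24-1.04 Hz for children.
#'
#' @param series list as returned by \code{\link{ibi_to_uniform}}.
#' @param role \code{"mother"} or \code{"child"}; sets the default band.
#' @param band optional length-2 Hz vector overriding the role default.
#' @return the input list with \code{values} replaced by the filtered series
#'   (zero mean).
#' @export
bandpass_respiratory <- function(series, role = c("mother", "child"),
                                 band = NULL) {
  role <- match.arg(role)
  band <- band %||% if (role == "mother") c(0.12, 0.40) else c(0.24, 1.04)
  if (series$rate <= 2 * band[2])
    stop(sprintf("sampling rate %g Hz must exceed twice the band upper edge %g Hz",
                 series$rate, band[2]))
  series$values <- butter_bandpass(series$values, series$rate, band)
  series$band <- band
  series
}

#' Continuous RSA: log variance in a sliding window
#'
#' At each 1 Hz output time the RSA value is the natural log of the variance
#' of the band-passed heart period within a centred 15-s window (truncated at
#' the series edges so a 300-s task yields exactly 300 samples). A variance
#' floor keeps the log finite on silent stretches.
#'
#' @param series filtered series from \code{\link{bandpass_respiratory}}.
#' @param window window length, seconds (default 15).
#' @param out_rate output rate, Hz (default 1).
#' @param variance_floor minimum variance, ms^2 (default 1e-6).
#' @return object of class \code{rsa_series} with \code{values} (ln ms^2),
#'   \code{timestamps} (s), \code{window}, \code{variance_floor}.
#' @export
continuous_rsa <- function(series, window = 15, out_rate = 1,
                           variance_floor = 1e-6) {
  x <- series$values
  rate <- series$rate
  n <- length(x)
  if (n < window * rate) stop("window longer than series")
  t0 <- series$time[1]
  duration <- (n - 1) / rate
  out_t <- seq(0, floor(duration), by = 1 / out_rate)
  half <- window / 2
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  lo <- pmax(1L, ceiling((out_t - half) * rate) + 1L)
  hi <- pmin(n, floor((out_t + half) * rate) + 1L)
  m <- hi - lo + 1L
  sx <- cs[hi + 1L] - cs[lo]
  sx2 <- cs2[hi + 1L] - cs2[lo]
  v <- (sx2 - sx^2 / m) / (m - 1)
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  structure(list(values = log(pmax(v, variance_floor)),
                 timestamps = out_t + t0, rate = out_rate,
                 window = window, variance_floor = variance_floor),
            class = "rsa_series")
}

#' @export
print.rsa_series <- function(x, ...) {
  cat(sprintf("rsa_series: %d samples at %g Hz, window %g s\n",
              length(x$values), x$rate, x$window))
  cat(sprintf("  RSA mean %.2f ln(ms^2), range [%.2f, %.2f]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Aggregate continuous RSA into fixed-size epochs
#'
#' Averages consecutive complete blocks of \code{block} samples (trailing
#' partial block discarded). With 1 Hz RSA over a 300-s task and the default
#' 29-sample block this yields 10 epochs, the closest approximation to
#' 30-second epochs.
#'
#' @param rsa an \code{rsa_series}.
#' @param block samples per epoch (default 29).
#' @return object of class \code{rsa_epochs} with \code{epoch_means} and
#'   \code{n_epochs}.
#' @export
epoch_rsa <- function(rsa, block = 29L) {
  stopifnot(inherits(rsa, "rsa_series"), block >= 1)
  v <- rsa$values
  block <- as.integer(block)
  n_epochs <- length(v) %/% block
  if (n_epochs < 1) stop("fewer samples than one block")
  m <- matrix(v[seq_len(n_epochs * block)], nrow = block)
  structure(list(epoch_means = colMeans(m), n_epochs = n_epochs,
                 block = as.integer(block)),
            class = "rsa_epochs")
}

#' Baseline RSA reference value
#'
#' Mean of the final 29 samples of the baseline RSA series; used as the
#' reference point that the dyadic coupling model subtracts from every epoch.
#'
#' @param rsa_baseline an \code{rsa_series} computed on the baseline segment,
#'   with at least 29 samples.
#' @param n_tail number of trailing samples to average (default 29).
#' @return scalar, ln(ms^2).
#' @export
baseline_reference <- function(rsa_baseline, n_tail = 29L) {
  stopifnot(inherits(rsa_baseline, "rsa_series"))
  v <- rsa_baseline$values
  if (length(v) < n_tail)
    stop(sprintf("baseline has %d samples; need >= %d", length(v), n_tail))
  mean(v[(length(v) - n_tail + 1L):length(v)])
}

#' Full cardiac branch for one person
#'
#' Convenience wrapper: artifact correction, uniform resampling, respiratory
#' band-pass, continuous RSA, task epochs and baseline reference.
#'
#' @param ibi an \code{ibi_series} containing baseline and task segments.
#' @param role passed to \code{\link{bandpass_respiratory}}.
#' @param band optional band override.
#' @param block epoch block size.
#' @return list with \code{epochs} (\code{rsa_epochs}), \code{baseline}
#'   (scalar reference), \code{rsa_task}, \code{rsa_baseline}, and
#'   \code{usable}.
#' @export
rsa_branch <- function(ibi, role = ibi$role, band = NULL, block = 29L) {
  corrected <- correct_ibi_artifacts(ibi)
  if (!corrected$usable)
    return(list(usable = FALSE, reason = corrected$reason))
  one <- function(seg) {
    u <- ibi_to_uniform(ibi_segment(corrected, seg))
    continuous_rsa(bandpass_respiratory(u, role = role, band = band))
  }
  rsa_task <- one("task")
  rsa_base <- one("baseline")
  list(usable = TRUE,
       epochs = epoch_rsa(rsa_task, block = block),
       baseline = baseline_reference(rsa_base),
       rsa_task = rsa_task, rsa_baseline = rsa_base)
}
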
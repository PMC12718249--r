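# Synthetic mother-child cohort generator.
#
# Every observable the analysis consumes (beat times, two-wavelength fNIRS
# intensities, behavioral scores) is generated with controllable effect sizes
# and stored alongside the generating truths, which are kept separate from
# the observables.

#' Generate one dyad's coupled interbeat-interval series
#'
#' Each partner's heart period is mean IBI + a respiratory-band sinusoid whose
#' slow (0.01-0.05 Hz) log-amplitude envelope is shared across partners in
#' proportion to \code{coupling}, plus white beat-to-beat jitter. Beat times
#' are cumulative sums of the IBIs. Epoch-scale RSA therefore covaries within
#' the dyad with strength controlled by \code{coupling}, without modelling
#' full cardiorespiratory physiology.
#'
#' @param config a \code{\link{sim_config}}.
#' @param coupling dimensionless envelope coupling, clipped to [-1, 1].
#' @param seed integer substream seed.
#' @return list with \code{mother} and \code{child} \code{\link{ibi_series}}.
#' @export
generate_dyad_ibi <- function(config, coupling, seed) {
  stopifnot(is.finite(coupling))
  c0 <- clip(coupling, -1, 1)
  total <- config$baseline_duration + config$task_duration
  with_seed(seed, {
    tg <- seq(0, total + 5, by = 0.25)
    e_shared <- band_limited_noise(tg, 0.01, 0.05)
    e_ind <- band_limited_noise(tg, 0.01, 0.05)
    person <- function(role) {
      env <- if (role == "mother") e_shared
             else c0 * e_shared + sqrt(1 - c0^2) * e_ind
      amp <- if (role == "mother") config$rsa_amp_mother else config$rsa_amp_child
      f <- if (role == "mother") config$resp_freq_mother else config$resp_freq_child
      mu <- if (role == "mother") config$ibi_mean_mother else config$ibi_mean_child
      phi <- stats::runif(1, 0, 2 * pi)
      env_f <- stats::approxfun(tg, amp * exp(0.5 * env), rule = 2)
      n_max <- ceiling(total / (0.2)) + 10L
      bt <- numeric(n_max)
      t <- 0; k <- 1L
      while (t < total) {
        ib <- mu + env_f(t) * sin(2 * pi * f * t + phi) +
          stats::rnorm(1, 0, config$ibi_jitter_sd)
        if (ib < 200)
          stop("generation error: IBI fell below 200 ms; reduce amplitudes")
        t <- t + ib / 1000
        k <- k + 1L
        bt[k] <- t
      }
      ibi_series(bt[seq_len(k)], baseline_duration = config$baseline_duration,
                 role = role)
    }
    list(mother = person("mother"), child = person("child"))
  })
}

# Tabulated extinction coefficients for hemoglobin, cm^-1 per (mole/liter),
# at the two measurement wavelengths (compiled from the standard tabulation
# distributed with common fNIRS processing toolchains).
#' Hemoglobin extinction coefficients
#' @return data.frame with columns wavelength_nm, e_hbo, e_hbr
#'   (cm^-1 M^-1).
#' @export
extinction_coefficients <- function() {
  data.frame(wavelength_nm = c(760, 850),
             e_hbo = c(1486.5865, 2526.391),
             e_hbr = c(3843.707, 1798.643))
}

#' Differential pathlength factor from age and wavelength
#'
#' General age-dependent DPF formula for continuous-wave NIRS.
#' @param wavelength_nm wavelength, nm.
#' @param age_years participant age.
#' @return dimensionless DPF.
#' @export
dpf_for_age <- function(wavelength_nm, age_years) {
  223.3 + 0.05624 * age_years^0.8493 -
    5.723e-7 * wavelength_nm^3 + 0.001245 * wavelength_nm^2 -
    0.9025 * wavelength_nm
}

# Forward modified Beer-Lambert matrix: od = A %*% c(hbo_M, hbr_M)
mbll_matrix <- function(distance_cm, dpf) {
  ec <- extinction_coefficients()
  A <- cbind(ec$e_hbo, ec$e_hbr) * (distance_cm * dpf)
  dimnames(A) <- list(paste0("wl", ec$wavelength_nm), c("hbo", "hbr"))
  A
}

new_intensity_recording <- function(intensity, rate, channels, wavelengths,
                                    role, person_id = NA_character_,
                                    dyad_id = NA_character_) {
  structure(list(intensity = intensity, rate = rate,
                 time = (seq_len(dim(intensity)[3]) - 1) / rate,
                 channels = channels, wavelengths = wavelengths,
                 role = role, person_id = person_id, dyad_id = dyad_id),
            class = "intensity_recording")
}

#' @export
print.intensity_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("intensity_recording: %d channels x %d wavelengths x %d samples at %g Hz (%s)\n",
              d[1], d[2], d[3], x$rate, x$role))
  invisible(x)
}

# Underlying band-limited hemodynamic sources for one dyad (list of per-person
# per-region hbo/hbr series on a time grid).
hemo_truth_signals <- function(t, f) {
  mix <- function(z, u) sqrt(f) * z + sqrt(1 - f) * u
  regions <- c("left_dlPFC", "right_dlPFC")
  out <- list(mother = list(), child = list())
  for (r in regions) {
    z_hbo <- band_limited_noise(t, 0.02, 0.1)
    z_hbr <- band_limited_noise(t, 0.02, 0.1)
    for (p in c("mother", "child")) {
      u_hbo <- band_limited_noise(t, 0.02, 0.1)
      u_hbr <- band_limited_noise(t, 0.02, 0.1)
      out[[p]][[r]] <- list(hbo = mix(z_hbo, u_hbo), hbr = -mix(z_hbr, u_hbr))
    }
  }
  out
}

#' Generate one dyad's paired two-wavelength fNIRS intensity recordings
#'
#' Underlying oxygenated/deoxygenated hemoglobin changes per dlPFC hemisphere
#' are a \code{target_coherence}-weighted mixture of a common band-limited
#' (0.02-0.1 Hz) source and person-specific sources. Channel-level series add
#' Mayer-wave (~0.1 Hz), respiratory, cardiac and white physiological noise,
#' and are pushed through the forward modified Beer-Lambert model (same
#' extinction matrix the conversion inverts) to produce raw intensities, so
#' that intensity -> OD -> hemoglobin round-trips.
#'
#' @param config a \code{\link{sim_config}}.
#' @param target_coherence shared variance fraction in [0, 1].
#' @param seed integer substream seed.
#' @param noise_scale multiplier on all noise amplitudes (0 disables noise).
#' @return list with \code{mother}, \code{child}
#'   (\code{intensity_recording}s) and \code{truth} (per-person per-region
#'   concentration series plus the target coherence).
#' @export
generate_dyad_hemo <- function(config, target_coherence = config$shared_fraction,
                               seed, noise_scale = 1) {
  if (target_coherence < 0 || target_coherence > 1)
    stop_config("target_coherence", "must lie in [0, 1]")
  rate <- config$hemo_rate
  total <- config$baseline_duration + config$task_duration
  n <- floor(rate * total) + 1L
  t <- (seq_len(n) - 1) / rate
  na <- lapply(config$noise_amplitudes, function(a) a * noise_scale)
  nc <- config$n_channels_per_region
  regions <- rep(c("left_dlPFC", "right_dlPFC"), each = nc)
  channels <- data.frame(channel = seq_len(2 * nc), region = regions,
                         distance_cm = config$source_distance_cm)
  with_seed(seed, {
    truth <- hemo_truth_signals(t, target_coherence)
    person <- function(role) {
      age <- if (role == "mother") config$mother_age else config$child_age
      resp_f <- if (role == "mother") config$resp_freq_mother else config$resp_freq_child
      card_f <- if (role == "mother") 1.0 else 1.4
      dpf <- dpf_for_age(c(760, 850), age)
      A <- mbll_matrix(config$source_distance_cm, dpf)
      intensity <- array(NA_real_, dim = c(2 * nc, 2, n))
      for (ch in seq_len(2 * nc)) {
        r <- regions[ch]
        noise <- function(amp_scale) {
          na$mayer * amp_scale * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi)) +
          na$respiration * amp_scale * sin(2 * pi * resp_f * t + stats::runif(1, 0, 2 * pi)) +
          na$cardiac * amp_scale * sin(2 * pi * card_f * t + stats::runif(1, 0, 2 * pi)) +
          na$white * amp_scale * stats::rnorm(n)
        }
        hbo <- config$hemo_amp_hbo * truth[[role]][[r]]$hbo + noise(1)
        hbr <- config$hemo_amp_hbr * truth[[role]][[r]]$hbr + noise(0.5)
        od <- A %*% rbind(hbo, hbr) * 1e-6   # concentrations in micromolar
        I <- exp(-od)                        # reference intensity 1 (a.u.)
        if (any(I <= 0)) stop("generation error: nonphysical nonpositive intensity")
        intensity[ch, 1, ] <- I[1, ]
        intensity[ch, 2, ] <- I[2, ]
      }
      new_intensity_recording(intensity, rate, channels, c(760, 850), role)
    }
    rec <- list(mother = person("mother"), child = person("child"),
                truth = c(truth, list(target_coherence = target_coherence)))
    if (config$motion_rate > 0) {
      for (p in c("mother", "child")) {
        corr <- inject_motion_artifacts(rec[[p]], config$motion_rate,
                                        seed = derive_seed(seed, match(p, c("mother", "child"))))
        rec[[p]] <- corr$recording
        rec$truth[[paste0("artifact_mask_", p)]] <- corr$mask
      }
    }
    rec
  })
}

#' Generate region-level hemodynamic series directly at 1 Hz
#'
#' Lightweight variant of \code{\link{generate_dyad_hemo}} used for
#' Monte-Carlo studies of the coherence and permutation machinery: it emits
#' the per-person region series (signal plus in-band white noise) on a 1 Hz
#' grid, skipping the optical forward model and channel structure.
#'
#' @param config a \code{\link{sim_config}}.
#' @param target_coherence shared variance fraction in [0, 1].
#' @param seed substream seed.
#' @param n_samples series length (default the task duration at 1 Hz).
#' @param noise_sd SD of additive white noise on each region series.
#' @return nested list \code{person -> region -> list(hbo, hbr)}.
#' @export
generate_region_series <- function(config, target_coherence = config$shared_fraction,
                                   seed, n_samples = config$task_duration,
                                   noise_sd = 0.3) {
  t <- seq_len(n_samples) - 1
  with_seed(seed, {
    truth <- hemo_truth_signals(t, target_coherence)
    for (p in c("mother", "child"))
      for (r in names(truth[[p]]))
        for (ch in c("hbo", "hbr"))
          truth[[p]][[r]][[ch]] <- truth[[p]][[r]][[ch]] +
            stats::rnorm(n_samples, 0, noise_sd)
    truth
  })
}

#' Inject motion artifacts into a recording
#'
#' Adds spike transients (amplitude at least 5 signal SDs, duration 0.5-2 s,
#' exponential decay) and step baseline shifts at Poisson-distributed event
#' times, common-mode across channels, and returns the per-sample corruption
#' mask. For intensity recordings the artifacts act on log-intensity
#' (multiplicative in intensity), matching how movement perturbs optical
#' coupling.
#'
#' @param recording an \code{intensity_recording}, or a numeric vector with a
#'   \code{rate} attribute (Hz).
#' @param rate_per_min expected artifacts per minute.
#' @param seed substream seed.
#' @return list \code{recording} (corrupted), \code{mask} (logical per
#'   sample), \code{n_events}.
#' @export
inject_motion_artifacts <- function(recording, rate_per_min, seed) {
  if (rate_per_min < 0) stop_config("motion_rate", "must be >= 0")
  is_rec <- inherits(recording, "intensity_recording")
  srate <- if (is_rec) recording$rate else attr(recording, "rate") %||% 1
  n <- if (is_rec) dim(recording$intensity)[3] else length(recording)
  mask <- rep(FALSE, n)
  if (rate_per_min == 0)
    return(list(recording = recording, mask = mask, n_events = 0L))
  with_seed(seed, {
    dur_min <- n / srate / 60
    n_events <- stats::rpois(1, rate_per_min * dur_min)
    artifact <- numeric(n)
    if (n_events > 0) {
      starts <- sort(sample.int(n, n_events, replace = TRUE))
      for (s in starts) {
        if (stats::runif(1) < 0.5) {                     # spike
          len <- round(stats::runif(1, 0.5, 2) * srate)
          idx <- s:min(n, s + len)
          amp <- sample(c(-1, 1), 1) * stats::runif(1, 5, 8)
          artifact[idx] <- artifact[idx] +
            amp * exp(-(seq_along(idx) - 1) / (len / 3))
          mask[idx] <- TRUE
        } else {                                          # step shift
          amp <- sample(c(-1, 1), 1) * stats::runif(1, 2, 5)
          artifact[s:n] <- artifact[s:n] + amp
          mask[s:min(n, s + round(srate))] <- TRUE
        }
      }
    }
    if (is_rec) {
      d <- dim(recording$intensity)
      for (ch in seq_len(d[1])) for (wl in seq_len(d[2])) {
        x <- recording$intensity[ch, wl, ]
        sdl <- stats::sd(log(x))
        recording$intensity[ch, wl, ] <- x * exp(artifact * sdl)
      }
    } else {
      recording <- recording + artifact * stats::sd(recording)
    }
    list(recording = recording, mask = mask, n_events = n_events)
  })
}

#' Generate the behavioral table from synchrony truths
#'
#' Child dysregulation follows the moderation generating equation
#' \deqn{dys = b0 + b_{pa} PA_c + b_{na} NA_c + b_{sync} s_c +
#'   b_{pa x sync} PA_c s_c + b_{gender} g_c + b_{income} inc_c + \epsilon}
#' where the \code{_c} subscript denotes centering at the sample mean (so the
#' generating coefficients are exactly the ones a mean-centered moderation
#' fit estimates). Maternal positive/negative affect are drawn at the PANAS
#' scale of the study population; gender is Bernoulli (girl = 1) and income
#' one of four ordered bands.
#'
#' @param sync numeric vector of per-dyad synchrony truths, or a
#'   \code{dyad_cohort} (its RSA coupling truths are used).
#' @param config a \code{\link{sim_config}}.
#' @param seed substream seed; per-row sub-seeds keep early rows stable when
#'   the cohort grows.
#' @return data.frame with dyad_id, pa, na, gender, income, sync,
#'   dysregulation.
#' @export
generate_behavior <- function(sync, config, seed = config$seed) {
  if (inherits(sync, "dyad_cohort")) sync <- sync$truths$coupling
  n <- length(sync)
  pa <- numeric(n); na_ <- numeric(n); g <- integer(n); inc <- integer(n)
  eps <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(seed, i), {
      pa[i] <- stats::rnorm(1, config$pa_mean, config$pa_sd)
      na_[i] <- stats::rnorm(1, config$na_mean, config$na_sd)
      g[i] <- stats::rbinom(1, 1, config$p_girl)
      inc[i] <- sample.int(4, 1, prob = config$income_probs)
      eps[i] <- stats::rnorm(1, 0, config$behavior_noise_sd)
    })
  }
  b <- config$behavior_coefs
  ctr <- function(x) x - mean(x)
  dys <- b$b0 + b$b_pa * ctr(pa) + b$b_na * ctr(na_) + b$b_sync * ctr(sync) +
    b$b_pa_x_sync * ctr(pa) * ctr(sync) +
    b$b_gender * ctr(g) + b$b_income * ctr(inc) + eps
  data.frame(dyad_id = sprintf("d%03d", seq_len(n)), pa = pa, na = na_,
             gender = g, income = inc, sync = sync, dysregulation = dys)
}

#' Generate a full synthetic cohort
#'
#' Draws per-dyad RSA envelope couplings and hemodynamic shared fractions,
#' generates every dyad's interbeat intervals and two-wavelength fNIRS
#' intensities from per-dyad seed substreams, and attaches the behavioral
#' table. Generating truths are stored separately from observables.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{dyad_cohort}: list with \code{config},
#'   \code{dyads} (per dyad: ids, mother/child \code{ibi_series} and
#'   \code{intensity_recording}s), \code{behavior} and \code{truths}.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_dyads
  dyad_seeds <- with_seed(config$seed, sample.int(2147483646L, n))
  couplings <- numeric(n); fractions <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(dyad_seeds[i], 0L), {
      couplings[i] <- stats::rnorm(1, config$rsa_coupling_mean, config$rsa_coupling_sd)
      fractions[i] <- clip(stats::rnorm(1, config$shared_fraction,
                                        config$shared_fraction_sd), 0, 1)
    })
  }
  dyads <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("d%03d", i)
    ibi <- generate_dyad_ibi(config, couplings[i], seed = derive_seed(dyad_seeds[i], 1L))
    hemo <- generate_dyad_hemo(config, fractions[i], seed = derive_seed(dyad_seeds[i], 2L))
    for (p in c("mother", "child")) {
      ibi[[p]]$dyad_id <- id; ibi[[p]]$person_id <- paste0(id, "_", p)
      hemo[[p]]$dyad_id <- id; hemo[[p]]$person_id <- paste0(id, "_", p)
    }
    dyads[[i]] <- list(dyad_id = id, ibi_mother = ibi$mother,
                       ibi_child = ibi$child, hemo_mother = hemo$mother,
                       hemo_child = hemo$child, hemo_truth = hemo$truth)
  }
  behavior <- generate_behavior(couplings, config, seed = config$seed)
  truths <- data.frame(dyad_id = sprintf("d%03d", seq_len(n)),
                       coupling = couplings, shared_fraction = fractions)
  structure(list(config = config, dyads = dyads, behavior = behavior,
                 truths = truths),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("dyad_cohort: %d dyads (seed %d)\n", length(x$dyads), x$config$seed))
  cat(sprintf("  RSA coupling truths: mean %.3f, sd %.3f\n",
              mean(x$truths$coupling), stats::sd(x$truths$coupling)))
  cat(sprintf("  shared hemo fraction: mean %.2f\n", mean(x$truths$shared_fraction)))
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' Layout: \code{behavior.csv}, \code{truths.csv}, and per dyad
#' \code{<id>_beats.csv} (role, beat_time_s) plus
#' \code{<id>_intensity_<role>.csv} (time_s, channel, wavelength_nm,
#' intensity).
#' @param cohort a \code{dyad_cohort}.
#' @param dir output directory (created if needed).
#' @param intensities write the (large) intensity CSVs too (default TRUE).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, intensities = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(cohort$truths, file.path(dir, "truths.csv"), row.names = FALSE)
  for (d in cohort$dyads) {
    beats <- rbind(
      data.frame(role = "mother", beat_time_s = d$ibi_mother$beat_times),
      data.frame(role = "child", beat_time_s = d$ibi_child$beat_times))
    utils::write.csv(beats, file.path(dir, paste0(d$dyad_id, "_beats.csv")),
                     row.names = FALSE)
    if (intensities) for (p in c("mother", "child")) {
      rec <- d[[paste0("hemo_", p)]]
      dd <- dim(rec$intensity)
      long <- data.frame(
        time_s = rep(rec$time, each = dd[1] * dd[2]),
        channel = rep(rec$channels$channel, times = dd[2] * dd[3]),
        wavelength_nm = rep(rep(rec$wavelengths, each = dd[1]), times = dd[3]),
        intensity = as.vector(rec$intensity))
      utils::write.csv(long, file.path(dir, paste0(d$dyad_id, "_intensity_", p, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read beat-time CSV into mother/child IBI series
#' @param path CSV with columns role, beat_time_s.
#' @param baseline_duration seconds.
#' @param dyad_id identifier attached to the series.
#' @return list with \code{mother} and \code{child} \code{ibi_series}.
#' @export
read_beats <- function(path, baseline_duration = 120, dyad_id = NA_character_) {
  df <- utils::read.csv(path)
  out <- lapply(c("mother", "child"), function(r)
    ibi_series(df$beat_time_s[df$role == r], baseline_duration = baseline_duration,
               dyad_id = dyad_id, role = r))
  names(out) <- c("mother", "child")
  out
}

#' Read an intensity CSV into an intensity_recording
#' @param path CSV with columns time_s, channel, wavelength_nm, intensity.
#' @param config a \code{\link{sim_config}} supplying channel geometry.
#' @param role \code{"mother"} or \code{"child"}.
#' @return an \code{intensity_recording}.
#' @export
read_intensity <- function(path, config, role = c("mother", "child")) {
  role <- match.arg(role)
  df <- utils::read.csv(path)
  chs <- sort(unique(df$channel)); wls <- sort(unique(df$wavelength_nm))
  ts <- sort(unique(df$time_s))
  arr <- array(NA_real_, dim = c(length(chs), length(wls), length(ts)))
  df <- df[order(df$time_s, df$wavelength_nm, df$channel), ]
  arr[] <- df$intensity  # channel fastest, then wavelength, then time
  nc <- config$n_channels_per_region
  channels <- data.frame(channel = chs,
                         region = rep(c("left_dlPFC", "right_dlPFC"), each = nc),
                         distance_cm = config$source_distance_cm)
  rate <- 1 / stats::median(diff(ts))
  new_intensity_recording(arr, rate, channels, wls, role)
}
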
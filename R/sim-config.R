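#' Configuration for the synthetic mother-child cohort generator
#'
#' Bundles every knob of the simulator: cohort size, task timing, cardiac and
#' respiratory parameters, hemodynamic coupling, noise amplitudes, motion
#' artifact rate, and the coefficients of the behavioral generating model.
#' Defaults reproduce the study conditions the analysis pipeline assumes:
#' a 2-minute resting baseline followed by a 5-minute dyadic stress task,
#' 7.81 Hz two-wavelength fNIRS over 4 channels per dorsolateral prefrontal
#' hemisphere, maternal PANAS positive/negative affect on their published
#' scales, and a child-dysregulation outcome generated from a moderation
#' equation whose interaction coefficient defaults to the negative
#' positive-affect-by-synchrony direction.
#'
#' @param n_dyads number of mother-child dyads (>= 4).
#' @param seed integer seed; one global seed spawns per-dyad substreams so a
#'   cohort can be extended without reshuffling existing dyads.
#' @param task_duration,baseline_duration seconds (defaults 300 and 120).
#' @param ibi_mean_mother,ibi_mean_child mean interbeat interval, ms.
#' @param resp_freq_mother,resp_freq_child respiratory frequency, Hz. The
#'   child default (0.5 Hz) sits above the adult default (0.25 Hz),
#'   matching the distinct adult and child respiratory bands.
#' @param rsa_amp_mother,rsa_amp_child respiratory-band IBI modulation
#'   amplitude, ms.
#' @param ibi_jitter_sd white beat-to-beat jitter, ms.
#' @param rsa_coupling_mean,rsa_coupling_sd mean and SD of the per-dyad
#'   envelope coupling s_i (dimensionless, clipped to [-1, 1] when used as a
#'   mixing weight).
#' @param hemo_rate fNIRS sampling rate, Hz (default 7.81).
#' @param n_channels_per_region channels per dlPFC hemisphere (default 4).
#' @param shared_fraction mean proportion of hemodynamic variance in the
#'   0.02-0.1 Hz band shared within a dyad; controls band-of-interest
#'   wavelet coherence.
#' @param shared_fraction_sd per-dyad spread of the shared fraction (clipped
#'   to [0, 1]); nonzero so that true coherence varies across dyads and can
#'   carry behavioral moderation effects.
#' @param hemo_amp_hbo,hemo_amp_hbr amplitude of the oxygenated /
#'   deoxygenated functional signal, micromolar.
#' @param noise_amplitudes named list with elements \code{mayer} (~0.1 Hz),
#'   \code{respiration} (~0.2-0.3 Hz), \code{cardiac} (~1 Hz) and
#'   \code{white}, all in micromolar.
#' @param source_distance_cm source-detector separation.
#' @param mother_age,child_age years; set the differential pathlength factor.
#' @param motion_rate motion artifacts per minute (Poisson rate).
#' @param behavior_coefs named list \code{b0, b_pa, b_na, b_sync,
#'   b_pa_x_sync, b_gender, b_income} of the behavioral generating equation.
#' @param behavior_noise_sd residual SD of the dysregulation outcome.
#' @param pa_mean,pa_sd,na_mean,na_sd maternal positive/negative affect
#'   marginals (defaults 36.21 (6.78) and 19.54 (7.26)).
#' @param p_girl probability that the child is a girl (default 0.54).
#' @param income_probs probabilities of the four ordered income bands.
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(n_dyads = 8, seed = 1)
#' cfg$task_duration
#' @export
sim_config <- function(n_dyads = 80L,
                       seed = 1L,
                       task_duration = 300,
                       baseline_duration = 120,
                       ibi_mean_mother = 750,
                       ibi_mean_child = 600,
                       resp_freq_mother = 0.25,
                       resp_freq_child = 0.5,
                       rsa_amp_mother = 40,
                       rsa_amp_child = 30,
                       ibi_jitter_sd = 5,
                       rsa_coupling_mean = -0.01,
                       rsa_coupling_sd = 0.03,
                       hemo_rate = 7.81,
                       n_channels_per_region = 4L,
                       shared_fraction = 0.5,
                       shared_fraction_sd = 0.15,
                       hemo_amp_hbo = 0.5,
                       hemo_amp_hbr = 0.2,
                       noise_amplitudes = list(mayer = 0.10, respiration = 0.08,
                                               cardiac = 0.05, white = 0.10),
                       source_distance_cm = 3,
                       mother_age = 36,
                       child_age = 6,
                       motion_rate = 0,
                       behavior_coefs = list(b0 = 1.79, b_pa = -0.01, b_na = 0.02,
                                             b_sync = -3, b_pa_x_sync = -0.47,
                                             b_gender = 0.02, b_income = 0.01),
                       behavior_noise_sd = 0.30,
                       pa_mean = 36.21, pa_sd = 6.78,
                       na_mean = 19.54, na_sd = 7.26,
                       p_girl = 0.54,
                       income_probs = c(0.113, 0.313, 0.237, 0.337)) {
  cfg <- list(
    n_dyads = as.integer(n_dyads), seed = as.integer(seed),
    task_duration = task_duration, baseline_duration = baseline_duration,
    ibi_mean_mother = ibi_mean_mother, ibi_mean_child = ibi_mean_child,
    resp_freq_mother = resp_freq_mother, resp_freq_child = resp_freq_child,
    rsa_amp_mother = rsa_amp_mother, rsa_amp_child = rsa_amp_child,
    ibi_jitter_sd = ibi_jitter_sd,
    rsa_coupling_mean = rsa_coupling_mean, rsa_coupling_sd = rsa_coupling_sd,
    hemo_rate = hemo_rate, n_channels_per_region = as.integer(n_channels_per_region),
    shared_fraction = shared_fraction, shared_fraction_sd = shared_fraction_sd,
    hemo_amp_hbo = hemo_amp_hbo, hemo_amp_hbr = hemo_amp_hbr,
    noise_amplitudes = noise_amplitudes,
    source_distance_cm = source_distance_cm,
    mother_age = mother_age, child_age = child_age,
    motion_rate = motion_rate,
    behavior_coefs = behavior_coefs, behavior_noise_sd = behavior_noise_sd,
    pa_mean = pa_mean, pa_sd = pa_sd, na_mean = na_mean, na_sd = na_sd,
    p_girl = p_girl, income_probs = income_probs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_dyads) || cfg$n_dyads < 4)
    stop_config("n_dyads", "must be >= 4")
  if (!is.finite(cfg$seed)) stop_config("seed", "must be a finite integer")
  # durations must exceed the window lengths used downstream (15-s RSA window,
  # 29-sample epochs, 10-50 s coherence periods)
  if (cfg$task_duration < 60) stop_config("task_duration", "must be >= 60 s")
  if (cfg$baseline_duration < 30) stop_config("baseline_duration", "must be >= 30 s")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop_config("shared_fraction", "must lie in [0, 1]")
  if (cfg$shared_fraction_sd < 0) stop_config("shared_fraction_sd", "must be >= 0")
  for (f in c("ibi_mean_mother", "ibi_mean_child", "resp_freq_mother",
              "resp_freq_child", "hemo_rate", "source_distance_cm"))
    if (cfg[[f]] <= 0) stop_config(f, "must be > 0")
  if (cfg$motion_rate < 0) stop_config("motion_rate", "must be >= 0")
  need <- c("mayer", "respiration", "cardiac", "white")
  if (!all(need %in% names(cfg$noise_amplitudes)))
    stop_config("noise_amplitudes",
                paste("must name amplitudes:", paste(need, collapse = ", ")))
  if (any(unlist(cfg$noise_amplitudes) < 0))
    stop_config("noise_amplitudes", "amplitudes must be >= 0")
  needb <- c("b0", "b_pa", "b_na", "b_sync", "b_pa_x_sync", "b_gender", "b_income")
  if (!all(needb %in% names(cfg$behavior_coefs)))
    stop_config("behavior_coefs",
                paste("must name coefficients:", paste(needb, collapse = ", ")))
  if (cfg$behavior_noise_sd < 0) stop_config("behavior_noise_sd", "must be >= 0")
  if (abs(sum(cfg$income_probs) - 1) > 1e-6)
    stop_config("income_probs", "must sum to 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dyad cohort configuration\n")
  cat(sprintf("  dyads: %d  seed: %d\n", x$n_dyads, x$seed))
  cat(sprintf("  baseline %gs + task %gs; fNIRS %g Hz, %d channels/region\n",
              x$baseline_duration, x$task_duration, x$hemo_rate,
              x$n_channels_per_region))
  cat(sprintf("  RSA coupling ~ N(%.3g, %.3g); shared hemo fraction %.2f (sd %.2f)\n",
              x$rsa_coupling_mean, x$rsa_coupling_sd,
              x$shared_fraction, x$shared_fraction_sd))
  invisible(x)
}
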
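# Shared fixtures and independent oracles, all built in code.

# Small, fast simulation config for structural tests.
tiny_cfg <- function(...) {
  sim_config(n_dyads = 4, seed = 42, baseline_duration = 60,
             task_duration = 120, ...)
}

# Reduced scale grid for Monte-Carlo loops: periods start ~4 s and stop at
# 64 s, comfortably bracketing the 10-50 s band of interest.
fast_wspec <- function() wavelet_spec(s0 = 4, max_period = 64)

# Monte-Carlo reference values, frozen from 200-seed simulations:
# mean band-of-interest coherence between independent series.
WHITE_NOISE_FOI_BASELINE <- 0.349      # 300-sample white noise, COI excluded
SHARED0_REGION_BASELINE <- 0.365       # generator region series, shared = 0

# Brute-force oracle for the sliding-window log-variance RSA.
bf_continuous_rsa <- function(x, rate, window = 15, floor_ = 1e-6) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / rate
  out_t <- seq(0, floor((n - 1) / rate))
  vapply(out_t, function(t) {
    idx <- which(tt >= t - window / 2 - 1e-9 & tt <= t + window / 2 + 1e-9)
    log(max(stats::var(x[idx]), floor_))
  }, numeric(1))
}

# Brute-force block means.
bf_block_means <- function(x, block) {
  k <- length(x) %/% block
  vapply(seq_len(k), function(i) mean(x[((i - 1) * block + 1):(i * block)]),
         numeric(1))
}

# Minimal hand-built od_recording around a channel x time OD matrix (one
# wavelength duplicated) for exercising the motion-correction operators.
od_from_matrix <- function(m, rate = 7.81) {
  nch <- nrow(m)
  od <- array(0, dim = c(nch, 2, ncol(m)))
  od[, 1, ] <- m; od[, 2, ] <- m
  out <- structure(list(od = od, reference = matrix(1, nch, 2), rate = rate,
                        time = (seq_len(ncol(m)) - 1) / rate,
                        channels = data.frame(channel = seq_len(nch),
                                              region = rep("left_dlPFC", nch),
                                              distance_cm = 3),
                        wavelengths = c(760, 850), role = "mother",
                        person_id = NA_character_, dyad_id = NA_character_),
                   class = "od_recording")
  attr(out, "stages") <- "od"
  out
}

# Construct a moderation_fit-shaped object from stated coefficients and
# covariance, for probing the Johnson-Neyman solver against its grid oracle.
fake_moderation_fit <- function(b_iv, b_int, v11, v13, v33, df,
                                mod_mean = 0, mod_range = c(-3, 3),
                                alpha = 0.05) {
  V <- matrix(0, 3, 3,
              dimnames = list(c(".iv_c", ".mod_c", ".int"),
                              c(".iv_c", ".mod_c", ".int")))
  V[".iv_c", ".iv_c"] <- v11
  V[".iv_c", ".int"] <- V[".int", ".iv_c"] <- v13
  V[".int", ".int"] <- v33
  structure(list(coefficients = data.frame(term = c("iv", "mod", "iv:mod"),
                                           B = c(b_iv, 0, b_int)),
                 vcov = V, df2 = df, alpha = alpha, iv = "iv",
                 moderator = "mod", moderator_mean = mod_mean,
                 moderator_range = mod_range),
            class = "moderation_fit")
}

# Independent oracle: locate significance transitions of the simple slope by
# scanning a fine moderator grid with plain t-tests.
jn_grid_oracle <- function(fit, step = 1e-4) {
  V <- fit$vcov
  b1 <- fit$coefficients$B[fit$coefficients$term == fit$iv]
  b3 <- fit$coefficients$B[fit$coefficients$term == paste0(fit$iv, ":", fit$moderator)]
  m <- seq(fit$moderator_range[1] - fit$moderator_mean,
           fit$moderator_range[2] - fit$moderator_mean, by = step)
  theta <- b1 + b3 * m
  se <- sqrt(V[".iv_c", ".iv_c"] + 2 * m * V[".iv_c", ".int"] +
               m^2 * V[".int", ".int"])
  tc <- stats::qt(1 - fit$alpha / 2, fit$df2)
  sig <- abs(theta / se) > tc
  flips <- which(diff(sig) != 0)
  (m[flips] + m[flips + 1]) / 2 + fit$moderator_mean
}

# Random behavioral-style dataset with a moderated effect, for J-N testing.
random_moderation_fit <- function(seed) {
  set.seed(seed)
  n <- 50 + sample(0:40, 1)
  d <- data.frame(pa = stats::rnorm(n, 36, 7),
                  sync = stats::rnorm(n, stats::runif(1, -0.5, 0.5),
                                      stats::runif(1, 0.2, 1)),
                  na = stats::rnorm(n, 20, 7),
                  gender = stats::rbinom(n, 1, 0.5),
                  income = sample(1:4, n, replace = TRUE))
  b1 <- stats::rnorm(1, 0, 0.05); b3 <- stats::rnorm(1, 0, 0.1)
  d$dysregulation <- 1.8 + b1 * (d$pa - mean(d$pa)) +
    b3 * (d$pa - mean(d$pa)) * (d$sync - mean(d$sync)) +
    0.02 * d$na + stats::rnorm(n, 0, 0.35)
  fit_moderation(d, "pa", "sync", c("na", "gender", "income"))
}

# Narrowband test signal: random-phase sinusoids on a frequency comb.
band_limited_noise_oracle <- function(t, f_lo, f_hi, k = 16) {
  f <- seq(f_lo, f_hi, length.out = k)
  ph <- stats::runif(k, 0, 2 * pi)
  drop(cos(2 * pi * outer(t, f) + matrix(ph, length(t), k, byrow = TRUE)) %*%
         rep(1 / sqrt(k), k))
}

# Keep only one region / chromophore of a per-dyad region-series list, to
# shrink Monte-Carlo loops.
subset_region_series <- function(rs, region = "left_dlPFC", chrom = "hbo") {
  lapply(rs, function(pair)
    lapply(pair, function(per)
      stats::setNames(list(stats::setNames(list(per[[region]][[chrom]]), chrom)),
                      region)))
}
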
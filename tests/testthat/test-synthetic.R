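# Synthetic cohort generator: validation, determinism, and the statistical
# structure the downstream analysis assumes.

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_dyads = 2), "n_dyads")
  expect_error(sim_config(shared_fraction = 1.5), "shared_fraction")
  expect_error(sim_config(resp_freq_child = 0), "resp_freq_child")
  expect_error(sim_config(noise_amplitudes = list(mayer = 1)), "noise_amplitudes")
  expect_error(sim_config(behavior_coefs = list(b0 = 1)), "behavior_coefs")
  expect_error(sim_config(income_probs = c(1, 1, 1, 1)), "income_probs")
})

test_that("identical config and seed give bit-identical cohorts; early dyads are stable under extension", {
  cfg <- tiny_cfg()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  bigger <- generate_cohort(sim_config(n_dyads = 5, seed = 42,
                                       baseline_duration = 60,
                                       task_duration = 120))
  expect_identical(a$dyads[[1]], bigger$dyads[[1]])
  expect_identical(a$dyads[[4]]$ibi_child$ibis, bigger$dyads[[4]]$ibi_child$ibis)
})

test_that("coupled IBI generation: respiratory bands differ by role and envelope coupling drives epoch covariation", {
  cfg <- tiny_cfg(ibi_jitter_sd = 0)
  d <- generate_dyad_ibi(cfg, coupling = 1, seed = 5)
  # distinct respiratory peaks: child near 0.5 Hz, mother near 0.25 Hz
  peak <- function(ib, role) {
    u <- bandpass_respiratory(ibi_to_uniform(ibi_segment(ib, "task")), role)
    sp <- stats::spec.pgram(stats::ts(u$values, frequency = u$rate), plot = FALSE)
    sp$freq[which.max(sp$spec)]
  }
  expect_lt(abs(peak(d$mother, "mother") - cfg$resp_freq_mother), 0.05)
  expect_lt(abs(peak(d$child, "child") - cfg$resp_freq_child), 0.05)

  # coupling = 1, no jitter: shared envelope -> epoch RSA tracks across
  # partners and the per-dyad slope recovers the unit generating ratio
  long <- sim_config(n_dyads = 4, seed = 1, ibi_jitter_sd = 0)
  dd <- generate_dyad_ibi(long, coupling = 1, seed = 9)
  bm <- rsa_branch(dd$mother); bc <- rsa_branch(dd$child)
  expect_gt(stats::cor(bm$epochs$epoch_means, bc$epochs$epoch_means), 0.85)
  fit <- fit_dyadic_coupling(list(bm$epochs$epoch_means),
                             list(bc$epochs$epoch_means),
                             list(mother = bm$baseline, child = bc$baseline),
                             coupling_spec("per_dyad_ols"))
  expect_lt(abs(fit$estimates$slope - 1), 0.4)
})

test_that("uncoupled dyads give near-zero mean coupling slope", {
  cfg <- sim_config(n_dyads = 4, seed = 3, ibi_jitter_sd = 0)
  slopes <- vapply(1:6, function(i) {
    d <- generate_dyad_ibi(cfg, coupling = 0, seed = 100 + i)
    bm <- rsa_branch(d$mother); bc <- rsa_branch(d$child)
    fit_dyadic_coupling(list(bm$epochs$epoch_means),
                        list(bc$epochs$epoch_means),
                        list(mother = bm$baseline, child = bc$baseline),
                        coupling_spec("per_dyad_ols"))$estimates$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.25)
})

test_that("extreme modulation amplitudes that would push IBI below 200 ms abort generation", {
  cfg <- tiny_cfg(rsa_amp_mother = 600)
  expect_error(generate_dyad_ibi(cfg, 0, seed = 1), "200 ms")
})

test_that("behavioral generator hits the configured marginals and generating equation", {
  cfg <- sim_config(n_dyads = 80, seed = 7)
  # zero coefficients and zero noise give a constant outcome b0
  cfg0 <- sim_config(n_dyads = 80, seed = 7, behavior_noise_sd = 0,
                     behavior_coefs = list(b0 = 1.79, b_pa = 0, b_na = 0,
                                           b_sync = 0, b_pa_x_sync = 0,
                                           b_gender = 0, b_income = 0))
  b0 <- generate_behavior(rnorm(80, 0, 0.03), cfg0, seed = 1)
  expect_equal(b0$dysregulation, rep(1.79, 80))

  # marginals across replicate cohorts match the configured population scale
  reps <- 200
  stats_mat <- vapply(seq_len(reps), function(i) {
    b <- generate_behavior(stats::rnorm(80, -0.01, 0.03), cfg, seed = i)
    c(mean(b$pa), stats::sd(b$pa), mean(b$na), stats::sd(b$na),
      mean(b$dysregulation), stats::sd(b$dysregulation))
  }, numeric(6))
  m <- rowMeans(stats_mat)
  expect_lt(abs(m[1] - 36.21), 0.2)   # PA mean
  expect_lt(abs(m[2] - 6.78), 0.2)    # PA sd
  expect_lt(abs(m[3] - 19.54), 0.2)   # NA mean
  expect_lt(abs(m[4] - 7.26), 0.2)    # NA sd
  expect_lt(abs(m[5] - 1.79), 0.05)   # outcome mean
  expect_lt(abs(m[6] - 0.37), 0.08)   # outcome sd

  # noiseless generation with known coefficients is recovered exactly by the
  # moderation fit (exact linear-algebra oracle)
  cfg_nl <- sim_config(n_dyads = 80, seed = 11, behavior_noise_sd = 0)
  b <- generate_behavior(stats::rnorm(80, 0, 0.5), cfg_nl, seed = 2)
  fit <- fit_moderation(b, "pa", "sync", c("na", "gender", "income"))
  cf <- coef(fit)
  expect_equal(unname(cf["pa"]), cfg_nl$behavior_coefs$b_pa, tolerance = 1e-8)
  expect_equal(unname(cf["sync"]), cfg_nl$behavior_coefs$b_sync, tolerance = 1e-8)
  expect_equal(unname(cf["pa:sync"]), cfg_nl$behavior_coefs$b_pa_x_sync,
               tolerance = 1e-8)
  expect_equal(unname(cf["na"]), cfg_nl$behavior_coefs$b_na, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("motion artifact injection: zero rate is a no-op and event counts follow the Poisson law", {
  x <- structure(sin(seq(0, 60, by = 0.1)), rate = 10)
  none <- inject_motion_artifacts(x, 0, seed = 1)
  expect_identical(none$recording, x)
  expect_false(any(none$mask))
  # rate 6/min on a 5-minute series: expectation 30 events; the total over
  # 100 seeds must sit inside the 99% interval of Poisson(100 * 30)
  n <- 300 * 10
  y <- structure(stats::rnorm(n), rate = 10)
  counts <- vapply(1:100, function(i)
    inject_motion_artifacts(y, 6, seed = i)$n_events, integer(1))
  total <- sum(counts)
  expect_gt(total, stats::qpois(0.005, 3000))
  expect_lt(total, stats::qpois(0.995, 3000))
  one <- inject_motion_artifacts(y, 6, seed = 1)
  expect_true(any(one$mask))
  expect_gt(max(abs(one$recording - y)), 3 * stats::sd(y))
})

test_that("cohort written to CSV reads back faithfully", {
  cfg <- tiny_cfg()
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "behavior.csv")))
  beats <- read_beats(file.path(dir, "d001_beats.csv"),
                      baseline_duration = cfg$baseline_duration, dyad_id = "d001")
  expect_equal(beats$mother$ibis, co$dyads[[1]]$ibi_mother$ibis, tolerance = 1e-9)
  rec <- read_intensity(file.path(dir, "d001_intensity_child.csv"), cfg, "child")
  expect_equal(rec$intensity, co$dyads[[1]]$hemo_child$intensity, tolerance = 1e-9)
  expect_equal(rec$channels$region, co$dyads[[1]]$hemo_child$channels$region)
})
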
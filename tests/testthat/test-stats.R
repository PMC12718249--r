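# Moderation models, Johnson-Neyman probing, correlation table, and the
# random-pairing permutation machinery.

test_that("mean centering", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(rep(7, 5)), rep(0, 5))
  set.seed(15)
  v <- stats::rnorm(50)
  expect_equal(mean_center(v), v - mean(v), tolerance = 1e-12)
  expect_lt(abs(mean(mean_center(v))), 1e-12)
  expect_error(mean_center(c(NA, 1)), "finite")
})

test_that("moderation fit interpolates noiseless data exactly and reports the study layout", {
  set.seed(16)
  n <- 40
  d <- data.frame(iv = stats::rnorm(n, 10, 2), mod = stats::rnorm(n, 0, 1))
  ivc <- d$iv - mean(d$iv); mc <- d$mod - mean(d$mod)
  d$dysregulation <- 1 + 2 * ivc + 3 * mc + 4 * ivc * mc
  fit <- fit_moderation(d, "iv", "mod")
  expect_equal(unname(coef(fit)), c(1, 2, 3, 4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # six predictors (iv, moderator, interaction, three covariates): F(6, n-7)
  n2 <- 71
  d2 <- data.frame(pa = stats::rnorm(n2, 36, 7), sync = stats::rnorm(n2, 0, 0.03),
                   na = stats::rnorm(n2, 20, 7), gender = stats::rbinom(n2, 1, 0.5),
                   income = sample(1:4, n2, TRUE),
                   dysregulation = stats::rnorm(n2, 1.8, 0.4))
  f2 <- fit_moderation(d2, "pa", "sync", c("na", "gender", "income"))
  expect_equal(f2$df1, 6)
  expect_equal(f2$df2, 64)
  expect_equal(nrow(f2$coefficients), 7)

  # standardized beta = B * sd(x)/sd(y) on the analyzed sample
  mm <- stats::model.matrix(f2$lm)
  i <- which(f2$coefficients$term == "pa:sync")
  expect_equal(f2$coefficients$beta[i],
               f2$coefficients$B[i] * stats::sd(mm[, ".int"]) /
                 stats::sd(d2$dysregulation), tolerance = 1e-10)

  # listwise deletion
  d2$na[1:5] <- NA
  f3 <- fit_moderation(d2, "pa", "sync", c("na", "gender", "income"))
  expect_equal(f3$n, 66)
  expect_equal(f3$df2, 59)

  # collinear design is refused with the offending term named
  d2$dup <- d2$na
  expect_error(fit_moderation(d2, "pa", "sync", c("na", "dup", "gender")),
               "singular|collinear")
})

test_that("Johnson-Neyman boundaries agree with a fine grid scan of simple-slope t-tests", {
  # constructed coefficient sets, including the two-sided pattern seen for
  # positive-affect x synchrony moderation
  cases <- list(
    fake_moderation_fit(1, -2, 0.01, 0, 0.01, 60),
    fake_moderation_fit(-0.05, -0.4, 4e-4, 1e-5, 0.01, 64, mod_mean = -0.01,
                        mod_range = c(-0.12, 0.10)),
    fake_moderation_fit(0.3, 0.5, 0.02, -0.005, 0.03, 40, mod_range = c(-2, 2))
  )
  for (fit in cases) {
    jn <- johnson_neyman(fit)
    gb <- jn_grid_oracle(fit)
    jb <- jn$boundaries[jn$in_observed_range]
    expect_equal(length(jb), length(gb))
    if (length(gb)) expect_lt(max(abs(sort(jb) - sort(gb))), 1e-4)
  }
  # two-sided region pattern is reachable: significant negative slope above
  # one boundary and significant positive slope below another
  jn2 <- johnson_neyman(cases[[1]])
  reg <- jn2$regions
  expect_true(any(reg$significant & reg$sign == "negative"))
  expect_true(any(reg$significant & reg$sign == "positive"))

  # no interaction variance: degenerate single global region
  jd <- johnson_neyman(fake_moderation_fit(1, 0, 0.01, 0, 0, 60))
  expect_true(jd$degenerate)
  expect_equal(nrow(jd$regions), 1)
  expect_true(jd$regions$significant[1])
})

test_that("interaction p-values can be jointly BH-adjusted across models", {
  set.seed(19)
  fits <- lapply(1:4, function(i) {
    n <- 40
    d <- data.frame(iv = stats::rnorm(n), mod = stats::rnorm(n),
                    dysregulation = stats::rnorm(n))
    fit_moderation(d, "iv", "mod")
  })
  names(fits) <- paste0("m", 1:4)
  adj <- adjust_interaction_p(fits)
  expect_equal(adj$p_adj, stats::p.adjust(adj$p, "BH"))
  expect_true(all(adj$p_adj >= adj$p))
  # probing carries the interaction p so exploratory probes are labelled
  jn <- johnson_neyman(fits[[1]])
  expect_equal(jn$interaction_p,
               fits[[1]]$coefficients$p[grep(":", fits[[1]]$coefficients$term)])
})

test_that("correlation table matches closed forms", {
  set.seed(17)
  d <- data.frame(x = stats::rnorm(30))
  d$y <- -d$x
  d$z <- stats::rnorm(30)
  d$const <- 1
  ct <- correlation_table(d)
  expect_equal(ct$r["x", "x"], 1)
  expect_equal(ct$r["x", "y"], -1, tolerance = 1e-12)
  expect_equal(ct$r["x", "z"],
               sum((d$x - mean(d$x)) * (d$z - mean(d$z))) /
                 sqrt(sum((d$x - mean(d$x))^2) * sum((d$z - mean(d$z))^2)),
               tolerance = 1e-12)
  expect_true(is.na(ct$r["x", "const"]))
  expect_equal(ct$stars["x", "y"], "**")
  expect_equal(ct$descriptives$mean[1], mean(d$x))
})

test_that("random pairings are seeded derangements; n = 3 hits exactly the two derangements", {
  ids3 <- c("a", "b", "c")
  sch <- random_pairings(ids3, 40, seed = 21)
  der3 <- matrix(c(2, 3, 1, 3, 1, 2), nrow = 2, byrow = TRUE)
  for (k in 1:40)
    expect_true(any(apply(der3, 1, function(d) all(sch$pairings[k, ] == d))))
  # both derangements occur (uniform sampling)
  expect_gt(length(unique(apply(sch$pairings, 1, paste, collapse = ""))), 1)

  sch8 <- random_pairings(sprintf("d%d", 1:8), 50, seed = 5)
  expect_true(all(apply(sch8$pairings, 1, function(p) !any(p == 1:8))))
  expect_true(all(apply(sch8$pairings, 1, function(p) sort(p) == 1:8)))
  expect_identical(sch8$pairings,
                   random_pairings(sprintf("d%d", 1:8), 50, seed = 5)$pairings)
  ind <- random_pairings(sprintf("d%d", 1:8), 50, seed = 5, method = "independent")
  expect_true(all(apply(ind$pairings, 1, function(p) !any(p == 1:8))))
  expect_error(random_pairings(c("a", "b"), 10, 1), "at least 3")
})

test_that("pseudo coherence equals true coherence when every dyad shares one signal", {
  set.seed(22)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 300))
  rs <- lapply(1:4, function(i)
    list(mother = list(left_dlPFC = list(hbo = x)),
         child = list(left_dlPFC = list(hbo = x))))
  names(rs) <- sprintf("d%03d", 1:4)
  sch <- random_pairings(names(rs), 5, seed = 1)
  ps <- permuted_coherence(rs, sch, chromophores = "hbo")
  expect_true(all(abs(ps$pseudo_coherence - 1) < 1e-6))
  ps2 <- permuted_coherence(rs, sch, chromophores = "hbo")
  expect_identical(ps, ps2)   # seeded determinism
})

test_that("random pairing breaks a coupling-driven moderation interaction", {
  cfg <- tiny_cfg(behavior_coefs = list(b0 = 1.79, b_pa = -0.01, b_na = 0.02,
                                        b_sync = -0.6, b_pa_x_sync = -0.12,
                                        b_gender = 0.02, b_income = 0.01),
                  behavior_noise_sd = 0.25)
  ns_flags <- vapply(1:8, function(r) {
    n <- 16
    set.seed(300 + r)
    f_i <- pmin(pmax(stats::rnorm(n, 0.6, 0.18), 0), 1)
    rs <- lapply(seq_len(n), function(i)
      generate_region_series(cfg, target_coherence = f_i[i], seed = 900 * r + i))
    names(rs) <- sprintf("d%03d", seq_len(n))
    rs1 <- subset_region_series(rs)
    behav <- generate_behavior(f_i, cfg, seed = 300 + r)
    sch <- random_pairings(names(rs1), 4, seed = r)
    ps <- permuted_coherence(rs1, sch, chromophores = "hbo", spec = fast_wspec())
    fit <- permutation_check(behav, ps, iv = "pa",
                             covariates = c("na", "gender", "income"))
    fit$coefficients$p[fit$coefficients$term == "pa:pseudo_coherence"] > 0.05
  }, logical(1))
  expect_gte(mean(ns_flags), 0.75)
})
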
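# fNIRS preprocessing chain: optics, quality control, motion correction,
# filtering, downsampling and region aggregation.

test_that("optical density conversion matches its closed form", {
  cfg <- tiny_cfg()
  rec <- generate_dyad_hemo(cfg, 0.5, seed = 1)$mother
  od <- intensity_to_od(rec)
  # reference-mean OD is 0 by construction
  expect_lt(max(abs(apply(od$od, c(1, 2), function(x) mean(exp(-x)) - 1))), 1e-6)
  # brute-force -ln ratio
  ch <- 3; wl <- 2
  I <- rec$intensity[ch, wl, ]
  expect_equal(od$od[ch, wl, ], -log(I / mean(I)), tolerance = 1e-12)
  # single-sample closed form: I = Ibar/e gives OD 1
  rec2 <- rec
  m <- mean(rec2$intensity[1, 1, ])
  rec2$intensity[1, 1, 50] <- m / exp(1)
  od2 <- intensity_to_od(rec2)
  m2 <- mean(rec2$intensity[1, 1, ])
  expect_equal(od2$od[1, 1, 50], -log((m / exp(1)) / m2), tolerance = 1e-12)
  # nonpositive intensity names the channel
  rec3 <- rec
  rec3$intensity[5, 1, 10] <- -1
  expect_error(intensity_to_od(rec3), "channel.*5")
})

test_that("channel pruning flags flatlines and high-variation channels and tracks region validity", {
  cfg <- tiny_cfg()
  rec <- generate_dyad_hemo(cfg, 0.5, seed = 2)$mother
  q0 <- prune_channels(intensity_to_od(rec))
  expect_true(all(q0$usable))
  expect_true(all(attr(q0, "region_valid")))

  flat <- rec
  flat$intensity[2, , ] <- 1                      # dead channel
  noisy <- flat
  noisy$intensity[7, 1, ] <- noisy$intensity[7, 1, ] *
    exp(stats::rnorm(dim(rec$intensity)[3], 0, 0.4))  # CV blowout
  q <- prune_channels(intensity_to_od(noisy))
  expect_false(q$usable[2])
  expect_match(q$reason[2], "flatline")
  expect_false(q$usable[7])
  expect_match(q$reason[7], "high_cv")

  # region with < 2 usable channels becomes invalid
  crippled <- rec
  crippled$intensity[1:3, , ] <- 1
  qr <- prune_channels(intensity_to_od(crippled))
  expect_false(attr(qr, "region_valid")[["left_dlPFC"]])
  expect_true(attr(qr, "region_valid")[["right_dlPFC"]])
})

test_that("channel accounting reproduces the usable-data arithmetic", {
  acct <- channel_accounting(65, 80)
  expect_identical(acct$analyzed_channels, 1040L)
  expect_equal(acct$pct_usable, 81.25)
  expect_equal(acct$pct_excluded, 18.75)
  zero <- channel_accounting(0, 80)
  expect_identical(zero$analyzed_channels, 0L)
  expect_equal(zero$pct_usable, 0)
})

test_that("spline motion correction removes steps and reduces spike damage", {
  set.seed(8)
  rate <- 7.81
  n <- 2000
  base <- 0.3 * sin(2 * pi * 0.05 * (0:(n - 1)) / rate)
  clean <- od_from_matrix(rbind(base, base), rate)
  out0 <- spline_motion_correct(clean)
  expect_lt(max(abs(out0$od[1, 1, ] - base)), 1e-6)

  # step shift: level difference across the step reduced by >= 90%
  stepped <- base + c(rep(0, 1000), rep(2, 1000))
  ods <- od_from_matrix(rbind(stepped, base), rate)
  corr <- spline_motion_correct(ods)
  lvl <- function(x) mean(x[1050:1500]) - mean(x[500:950])
  expect_lt(abs(lvl(corr$od[1, 1, ])), 0.1 * abs(lvl(stepped)))

  # injected spikes: corrected series closer to the clean truth than corrupted
  spiky <- inject_motion_artifacts(structure(base, rate = rate), 6, seed = 3)
  odk <- od_from_matrix(rbind(spiky$recording, base), rate)
  fixed <- spline_motion_correct(odk)
  rmse <- function(x) sqrt(mean((x - base)^2))
  expect_lt(rmse(fixed$od[1, 1, ]), rmse(spiky$recording))

  # a channel flagged in its entirety is marked unusable, not corrected
  wild <- od_from_matrix(rbind(base, stats::rnorm(n, 0, 50)), rate)
  res <- spline_motion_correct(wild)
  expect_true(is.numeric(attr(res, "unusable_channels")) ||
                is.integer(attr(res, "unusable_channels")))
})

test_that("wavelet transform reconstructs perfectly and the IQR rule tames spikes", {
  set.seed(9)
  z <- stats::rnorm(512)
  w <- dwt_periodic(z, 5)
  expect_lt(max(abs(idwt_periodic(w) - z)), 1e-9)

  # Gaussian signal: nearly all detail coefficients retained, output ~ input
  smooth <- cumsum(stats::rnorm(1000)) / 10
  odg <- od_from_matrix(rbind(smooth, smooth), 7.81)
  outg <- wavelet_motion_correct(odg)
  expect_gt(stats::cor(outg$od[1, 1, ], smooth), 0.99)

  # single extreme spike attenuated by >= 80%
  spiked <- smooth
  spiked[500] <- spiked[500] + 30
  ods <- od_from_matrix(rbind(spiked, smooth), 7.81)
  outs <- wavelet_motion_correct(ods)
  resid <- outs$od[1, 1, 500] - smooth[500]
  expect_lt(abs(resid), 0.2 * 30)

  short <- od_from_matrix(matrix(stats::rnorm(80), 2), 7.81)
  short$od <- short$od[, , 1:30, drop = FALSE]
  expect_warning(wavelet_motion_correct(short), "skipped")
})

test_that("hemoglobin conversion inverts the forward optics exactly", {
  set.seed(10)
  n <- 400
  hbo_uM <- 0.4 * sin(2 * pi * 0.05 * (0:(n - 1)))
  hbr_uM <- -0.15 * cos(2 * pi * 0.03 * (0:(n - 1)))
  A <- dyadsync:::mbll_matrix(3, dpf_for_age(c(760, 850), 36))
  odm <- A %*% rbind(hbo_uM, hbr_uM) * 1e-6
  od <- od_from_matrix(matrix(0, 2, n), rate = 1)
  od$od[1, 1, ] <- odm[1, ]; od$od[1, 2, ] <- odm[2, ]
  od$od[2, 1, ] <- odm[1, ]; od$od[2, 2, ] <- odm[2, ]
  hemo <- od_to_hemoglobin(od, age = 36)
  expect_lt(max(abs(hemo$hbo[1, ] - hbo_uM)), 1e-9)
  expect_lt(max(abs(hemo$hbr[1, ] - hbr_uM)), 1e-9)
  expect_identical(hemo$hbt, hemo$hbo + hemo$hbr)
  # zero OD maps to zero concentration change
  zero <- od_from_matrix(matrix(0, 2, 100), rate = 1)
  hz <- od_to_hemoglobin(zero, age = 6)
  expect_true(all(hz$hbo == 0) && all(hz$hbr == 0))
})

test_that("hemodynamic band-pass and downsampling preserve in-band content and reject out-of-band", {
  rate <- 7.81
  n <- 4096
  t <- (0:(n - 1)) / rate
  mk_hemo <- function(x) {
    od <- od_from_matrix(rbind(x * 0, x * 0), rate)
    h <- od_to_hemoglobin(od, age = 36)
    h$hbo <- rbind(x, x); h$hbr <- -0.3 * h$hbo; h$hbt <- h$hbo + h$hbr
    h
  }
  # constant input -> ~0 after band-pass
  hc <- bandpass_hemo(mk_hemo(rep(1, n)))
  expect_lt(max(abs(hc$hbo)), 1e-6)
  # 0.05 Hz preserved within 5%
  hs <- bandpass_hemo(mk_hemo(sin(2 * pi * 0.05 * t)))
  amp <- (max(hs$hbo[1, 500:3500]) - min(hs$hbo[1, 500:3500])) / 2
  expect_lt(abs(amp - 1), 0.05)
  # 2 Hz attenuated by >= 20 dB
  hf <- bandpass_hemo(mk_hemo(sin(2 * pi * 2 * t)))
  ampf <- (max(hf$hbo[1, 500:3500]) - min(hf$hbo[1, 500:3500])) / 2
  expect_lt(20 * log10(ampf), -20)

  # downsampling: constant stays constant; 0.05 Hz amplitude within 2%
  hd <- downsample_hemo(mk_hemo(rep(0.7, n) + 0 * t), target = 1)
  expect_lt(max(abs(hd$hbo - 0.7)), 1e-3)
  expect_equal(hd$rate, 1)
  hds <- downsample_hemo(mk_hemo(sin(2 * pi * 0.05 * t)), target = 1)
  mid <- hds$hbo[1, 60:460]
  expect_lt(abs((max(mid) - min(mid)) / 2 - 1), 0.02)
  expect_error(downsample_hemo(mk_hemo(rep(1, n)), target = 10), "below")
})

test_that("region aggregation averages usable channels only", {
  cfg <- tiny_cfg()
  rec <- generate_dyad_hemo(cfg, 0.5, seed = 4)$mother
  hemo <- od_to_hemoglobin(intensity_to_od(rec), age = 36)
  rs <- aggregate_region(hemo)
  expect_equal(rs$left_dlPFC$hbo, colMeans(hemo$hbo[1:4, ]), tolerance = 1e-12)
  q <- prune_channels(intensity_to_od(rec))
  q$usable[1] <- FALSE
  rs2 <- aggregate_region(hemo, q)
  expect_equal(rs2$left_dlPFC$hbo, colMeans(hemo$hbo[2:4, ]), tolerance = 1e-12)
  q$usable[1:3] <- FALSE
  rs3 <- aggregate_region(hemo, q)
  expect_null(rs3$left_dlPFC)
  expect_identical(attr(rs3, "invalid_regions"), "left_dlPFC")
})

test_that("pipeline order is enforced: operations refuse to run twice", {
  cfg <- tiny_cfg()
  rec <- generate_dyad_hemo(cfg, 0.5, seed = 5)$mother
  od <- intensity_to_od(rec)
  od2 <- spline_motion_correct(od)
  expect_error(spline_motion_correct(od2), "already applied")
  od3 <- wavelet_motion_correct(od2)
  expect_error(wavelet_motion_correct(od3), "already applied")
  h <- od_to_hemoglobin(od3, age = 36)
  h2 <- downsample_hemo(h, 1)
  expect_error(downsample_hemo(h2, 0.5), "already applied")
})

test_that("generated concentrations survive the full forward/inverse chain", {
  cfg <- tiny_cfg()
  h <- generate_dyad_hemo(cfg, 1, seed = 6, noise_scale = 0)
  hemo <- od_to_hemoglobin(intensity_to_od(h$mother), age = cfg$mother_age)
  truth <- cfg$hemo_amp_hbo * h$truth$mother$left_dlPFC$hbo
  est <- hemo$hbo[1, ]
  expect_lt(max(abs((est - mean(est)) - (truth - mean(truth)))), 1e-6)
})
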
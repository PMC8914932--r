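test_that("zero-phase low-pass preserves DC, is linear, and kills high frequencies", {
  fs <- 200
  x_const <- rep(3.7, 400)
  expect_equal(lowpass_filter(x_const, fs), x_const, tolerance = 1e-9)
  set.seed(1)
  x <- rnorm(400); y <- rnorm(400)
  expect_equal(lowpass_filter(2.5 * x - 1.3 * y, fs),
               2.5 * lowpass_filter(x, fs) - 1.3 * lowpass_filter(y, fs),
               tolerance = 1e-9)
  # 60 Hz sinusoid through a 25 Hz 2nd-order Butterworth, applied twice
  # (forward-backward): analytic gain |H|^2 = 1/(1 + (f/fc)^4)
  t <- seq(0, 2, by = 1 / fs)
  f0 <- 60
  z <- lowpass_filter(sin(2 * pi * f0 * t), fs)
  gain <- max(abs(z[100:300]))  # steady-state interior
  expect_lt(gain, 0.05)
  expect_lt(gain, 1 / (1 + (f0 / 25)^4) * 1.2)
  expect_error(lowpass_filter(x, fs, cutoff = 150), "Nyquist")
})

test_that("stance resampling returns exactly n samples and is exact on lines", {
  t <- seq(0, 2, by = 0.01)
  x <- 3 + 2 * t
  out <- resample_stance(x, t, 0.5, 1.5, 1000)
  expect_length(out, 1000)
  expect_equal(out[1], 3 + 2 * 0.5, tolerance = 1e-9)
  expect_equal(out[1000], 3 + 2 * 1.5, tolerance = 1e-9)
  expect_equal(out, 3 + 2 * seq(0.5, 1.5, length.out = 1000),
               tolerance = 1e-9)
  expect_equal(resample_stance(rep(7, length(t)), t, 0.2, 1.1, 50),
               rep(7, 50), tolerance = 1e-12)
  expect_error(resample_stance(x, t, 1.5, 0.5), "to > hs")
})

test_that("event matching pairs identical and rigidly shifted lists", {
  ref <- gait_events(hs = c(1, 2.6, 4.2), to = c(2, 3.6, 5.2))
  mm <- match_events(ref, ref)
  expect_identical(nrow(mm$pairs), 6L)
  expect_true(all(mm$pairs$error == 0))
  expect_identical(nrow(mm$misses), 0L)
  det <- gait_events(hs = ref$hs + 0.02, to = ref$to + 0.02)
  mm2 <- match_events(det, ref)
  expect_true(all(abs(mm2$pairs$error - 0.02) < 1e-12))
  # a spurious extra stride is flagged as false alarms, not paired twice
  det3 <- gait_events(hs = c(0.2, ref$hs + 0.02),
                      to = c(0.3, ref$to + 0.02))
  mm3 <- match_events(det3, ref, max_gap = 0.5)
  expect_identical(nrow(mm3$false_alarms), 2L)
  expect_identical(nrow(mm3$pairs), 6L)
})

test_that("event matching agrees with the exhaustive minimum-cost oracle", {
  set.seed(55)
  for (i in 1:40) {
    ref <- sort(runif(sample(1:4, 1), 0, 10))
    det <- sort(runif(sample(1:4, 1), 0, 10))
    gap <- runif(1, 0.5, 3)
    got <- spfgait:::match_times(det, ref, gap)
    best <- oracle_match(det, ref, gap)
    expect_identical(length(got$ref_idx), as.integer(best$m))
    cost <- sum(abs(det[got$det_idx] - ref[got$ref_idx]))
    expect_equal(cost, best$cost, tolerance = 1e-12)
  }
})

test_that("timing-error statistics match hand computations and a quantile oracle", {
  s1 <- event_error_stats(c(0.02, 0.02, 0.02), stride_period = 1.6)
  expect_equal(s1$mae, 0.020, tolerance = 1e-12)
  expect_equal(s1$pct_late, 1.0)
  expect_equal(s1$mae_pct_stride, 100 * 0.02 / 1.6, tolerance = 1e-12)
  s2 <- event_error_stats(c(-0.01, 0.01), stride_period = 1.6)
  expect_equal(s2$pct_late, 0.5)
  set.seed(66)
  for (i in 1:50) {
    e <- rnorm(sample(3:40, 1), 0, 0.05)
    st <- event_error_stats(e, stride_period = 1.6)
    ae <- abs(e)
    expect_equal(st$mae, oracle_quantile(ae, 0.5), tolerance = 1e-12)
    expect_equal(st$iqr,
                 oracle_quantile(ae, 0.75) - oracle_quantile(ae, 0.25),
                 tolerance = 1e-12)
  }
  expect_error(event_error_stats(numeric(0), 1.6), "no matched")
})

test_that("stance durations pair each heel strike with its closing toe-off", {
  ev <- gait_events(hs = c(1.0), to = c(1.65))
  expect_equal(stance_durations(ev), 0.65, tolerance = 1e-12)
  ev2 <- gait_events(hs = c(1.0, 2.6), to = c(1.65))  # trailing HS unclosed
  expect_equal(stance_durations(ev2), 0.65, tolerance = 1e-12)
  expect_error(stance_durations(list(hs = 1, to = 2)), "gait_events")
})

test_that("waveform agreement matches the direct-formula oracle", {
  set.seed(77)
  a <- matrix(rnorm(5 * 100), 5)
  wa <- waveform_agreement(a, a)
  expect_equal(wa$pearson_r, 1, tolerance = 1e-12)
  expect_equal(wa$rmse, 0, tolerance = 1e-12)
  wb <- waveform_agreement(a, -a)
  expect_equal(wb$pearson_r, -1, tolerance = 1e-12)
  b <- matrix(rnorm(5 * 100), 5)
  wc <- waveform_agreement(a, b)
  expect_equal(wc$pearson_r, oracle_pearson(as.numeric(a), as.numeric(b)),
               tolerance = 1e-12)
  expect_equal(wc$rmse, sqrt(sum((a - b)^2) / length(a)), tolerance = 1e-12)
  # zero-variance input yields the undefined-correlation marker
  z <- matrix(1, 2, 10)
  expect_true(is.na(waveform_agreement(z, z)$pearson_r))
  expect_error(waveform_agreement(a, b[1:3, ]), "equal shapes")
})

test_that("mass-normalized peaks follow the scaling law", {
  stance <- matrix(700, 3, 100)
  pk <- peak_vgrf_normalized(stance, 70)
  expect_equal(pk$peaks, rep(10, 3), tolerance = 1e-12)
  expect_equal(peak_vgrf_normalized(stance, 140)$median, 5,
               tolerance = 1e-12)
  expect_error(peak_vgrf_normalized(stance, 0), "positive")
})

test_that("statistics are invariant to a global time shift of both event sets", {
  set.seed(88)
  hs0 <- cumsum(runif(6, 1.4, 1.8))
  ref <- gait_events(hs = hs0, to = hs0 + 1)
  det <- gait_events(hs = ref$hs + rnorm(6, 0.02, 0.01),
                     to = ref$to + rnorm(6, -0.02, 0.01))
  s0 <- event_error_stats(match_events(det, ref), 1.6)
  shift <- 13.7
  det_s <- gait_events(det$hs + shift, det$to + shift)
  ref_s <- gait_events(ref$hs + shift, ref$to + shift)
  s1 <- event_error_stats(match_events(det_s, ref_s), 1.6)
  expect_equal(s1$mae, s0$mae, tolerance = 1e-12)
  expect_equal(s1$iqr, s0$iqr, tolerance = 1e-12)
  expect_equal(s1$pct_late, s0$pct_late)
})

test_that("trial benchmark is complete and PS stance underestimates the true stance", {
  prm <- gait_profile_params(n_strides = 8, seed = 112)
  trial <- simulate_trial(prm)
  rep <- benchmark_trial(trial)
  expect_true(all(c("PS", "IMU") %in% rep$events$detector))
  expect_true(all(rep$events$mae >= 0))
  expect_identical(nrow(rep$stance), 2L)
  expect_true(all(c("vGRF", "CoPy") %in% rep$waveforms$variable))
  # both detectors underestimate the true stance duration: the force must
  # rise to the threshold after contact and falls below it before lift-off,
  # and the IMU impact peak lags contact
  st_true <- prm$duty_factor * prm$stride_period
  vg <- vgrf_series(trial$pressure$voltages, trial$config$poly,
                    trial$config$layout, trial$config$thr)
  for (ev in list(ps_segment(vg, t = trial$pressure$t, vGRFT = 15),
                  imu_segment(trial$imu))) {
    expect_lt(median(stance_durations(ev)), st_true)
  }
})
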
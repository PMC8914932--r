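test_that("stance force profile is a double bump vanishing at the boundaries", {
  expect_identical(synth_vgrf_profile(0, 70), 0)
  expect_identical(synth_vgrf_profile(1, 70), 0)
  ph <- seq(0, 1, length.out = 5001)
  f <- synth_vgrf_profile(ph, 70)
  expect_true(all(f >= 0))
  # dense-grid scan: count strict interior local maxima
  is_max <- f[2:5000] > f[1:4999] & f[2:5000] > f[3:5001]
  expect_identical(sum(is_max), 2L)
  expect_equal(max(f), 10.4 * 70, tolerance = 1e-4)
  expect_error(synth_vgrf_profile(1.2, 70), "\\[0, 1\\]")
  expect_error(synth_vgrf_profile(-0.1, 70), "\\[0, 1\\]")
})

test_that("center-of-pressure trajectory runs monotonically heel to toe", {
  layout <- default_tactel_layout()
  y0 <- synth_cop_trajectory(0)
  y1 <- synth_cop_trajectory(1)
  expect_true(y0 >= 0 && y0 <= 6)     # heel region
  expect_true(y1 >= 12 && y1 <= 22.8) # forefoot region
  y <- synth_cop_trajectory(seq(0, 1, length.out = 2001))
  expect_true(all(diff(y) >= 0))
  expect_error(synth_cop_trajectory(2), "\\[0, 1\\]")
})

test_that("force distribution hits the requested centroid exactly", {
  layout <- default_tactel_layout()
  expect_identical(distribute_to_tactels(0, 10, layout), rep(0, 16))
  # delta-kernel limit: all load on the tactel at the target
  f <- distribute_to_tactels(100, layout$yi[7], layout, kernel_width = 1e-9)
  expect_equal(f[7], 100)
  expect_equal(sum(f[-7]), 0)
  expect_error(distribute_to_tactels(100, -3, layout), "span")
  expect_error(distribute_to_tactels(-1, 10, layout), "nonnegative")
  set.seed(31)
  for (i in 1:300) {
    tot <- runif(1, 15, 800)
    cop <- runif(1, 2, 21)
    f <- distribute_to_tactels(tot, cop, layout)
    expect_true(all(f >= 0))
    expect_equal(sum(f), tot, tolerance = 1e-9)
    cen <- sum(f * layout$wyi * layout$yi) / sum(f * layout$wyi)
    expect_true(abs(cen - cop) < 1e-6)
  }
})

test_that("distribution respects a minimum-force floor without losing exactness", {
  layout <- default_tactel_layout()
  poly <- calibration_polynomial()
  thr <- sensing_thresholds()
  floor_f <- force_from_voltage(thr$VT, poly) * 1.01
  set.seed(32)
  for (i in 1:200) {
    tot <- runif(1, 15, 800)
    cop <- runif(1, 2, 21)
    f <- distribute_to_tactels(tot, cop, layout, min_force = floor_f)
    expect_true(all(f == 0 | f >= floor_f - 1e-9))
    expect_equal(sum(f), tot, tolerance = 1e-9)
    cen <- sum(f * layout$wyi * layout$yi) / sum(f * layout$wyi)
    expect_true(abs(cen - cop) < 1e-6)
    # round trip through the voltage chain and the CoPy estimator
    v <- rep(0, 16)
    nz <- f > 0
    v[nz] <- voltage_from_force(f[nz], poly)
    expect_true(abs(compute_copy(v, poly, layout, thr) - cop) < 1e-6)
  }
})

test_that("synthetic IMU morphology satisfies the detector assumptions", {
  prm <- gait_profile_params(n_strides = 3, seed = 1)
  # zero strides: constant gravity, no transients
  imu0 <- synth_imu_trace(gait_events(), prm)
  expect_true(all(imu0$wx == 0))
  expect_true(all(imu0$az == 9.81))
  sw <- (1 - prm$duty_factor) * prm$stride_period
  hs <- sw + (0:2) * prm$stride_period
  truth <- gait_events(hs, hs + prm$duty_factor * prm$stride_period)
  imu <- synth_imu_trace(truth, prm)
  # per-swing angular-velocity maxima clear the mid-swing threshold
  for (h in truth$hs) {
    seg <- imu$wx[imu$t >= h - sw & imu$t <= h]
    expect_gt(max(seg), 75)
  }
  # per-stride trough clears the toe-off threshold
  for (o in truth$to) {
    seg <- imu$wx[abs(imu$t - o) < 0.2]
    expect_lt(min(seg), -65)
  }
  # noise-free single-pass FSM recovers both events within the budget
  ev <- imu_segment(imu)
  expect_length(ev$hs, 3)
  expect_length(ev$to, 3)
  expect_true(all(abs(ev$hs - truth$hs) < 0.100))
  expect_true(all(abs(ev$to - truth$to) < 0.100))
})

test_that("simulated trials are bitwise reproducible for a fixed seed", {
  prm <- gait_profile_params(n_strides = 4, seed = 77)
  t1 <- simulate_trial(prm)
  t2 <- simulate_trial(prm)
  expect_identical(t1$pressure$voltages, t2$pressure$voltages)
  expect_identical(t1$fz$fz, t2$fz$fz)
  expect_identical(t1$imu$az, t2$imu$az)
  expect_identical(t1$truth, t2$truth)
  t3 <- simulate_trial(gait_profile_params(n_strides = 4, seed = 78))
  expect_false(identical(t1$fz$fz, t3$fz$fz))
})

test_that("trial bookkeeping and noise-free round trips hold", {
  prm <- gait_profile_params(n_strides = 10, seed = 9, noise_sd_voltage = 0,
                             noise_sd_accel = 0, noise_sd_gyro = 0,
                             noise_sd_force = 0)
  trial <- simulate_trial(prm)
  expect_length(trial$truth$hs, 10)
  expect_length(trial$truth$to, 10)
  # fz exceeds the 20 N reference threshold at every stance midpoint
  mid <- (trial$truth$hs + trial$truth$to) / 2
  fz_mid <- stats::approx(trial$fz$t, trial$fz$fz, xout = mid)$y
  expect_true(all(fz_mid > 20))
  # per-stride vGRF peak recovered through the full sensing chain
  vg <- vgrf_series(trial$pressure$voltages, trial$config$poly,
                    trial$config$layout, trial$config$thr)
  peak_true <- prm$peak_scale * prm$body_mass
  for (k in seq_len(10)) {
    ink <- trial$pressure$t >= trial$truth$hs[k] &
      trial$pressure$t <= trial$truth$to[k]
    expect_true(abs(max(vg[ink]) - peak_true) < 1)  # within 1 N
  }
  # during proper stance every emitted nonzero voltage is active (at or
  # below the gate); at barely-loaded onset/offset frames the distributor
  # may leave at most a gate-equivalent of force on an inactive tactel
  v <- trial$pressure$voltages
  thr <- trial$config$thr
  stance <- vg >= thr$vGRFT
  expect_true(all(v[stance, ][v[stance, ] != 0] <= thr$VT))
  floor_f <- force_from_voltage(thr$VT, trial$config$poly)
  leak <- apply(v, 1, function(r) {
    gated <- r != 0 & r > thr$VT
    if (!any(gated)) 0 else sum(force_from_voltage(r[gated],
                                                   trial$config$poly))
  })
  expect_true(all(leak <= 2 * floor_f))
})

test_that("noise-free stance duration matches the duty factor and truth is recoverable", {
  prm <- gait_profile_params(n_strides = 6, seed = 10, noise_sd_voltage = 0,
                             noise_sd_accel = 0, noise_sd_gyro = 0,
                             noise_sd_force = 0)
  trial <- simulate_trial(prm)
  dt_fp <- 1 / prm$fs_forceplate
  # vanishing threshold recovers ground truth within one force-plate sample
  ev <- suppressWarnings(ps_segment(trial$fz$fz, t = trial$fz$t,
                                    vGRFT = 1e-6))
  expect_true(all(abs(ev$hs - trial$truth$hs) <= dt_fp + 1e-9))
  expect_true(all(abs(ev$to - trial$truth$to) <= dt_fp + 1e-9))
  st <- stance_durations(trial$truth)
  expect_true(all(abs(st - prm$duty_factor * prm$stride_period) <= dt_fp))
})
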
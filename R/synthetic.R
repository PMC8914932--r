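#' Parameters of the synthetic gait generator
#'
#' Defines the study conditions a synthetic trial emulates: a steady walk at
#' a fixed stride period with a given stance fraction, the double-bump
#' vertical ground reaction force scaled so the force-plate peak is about
#' `peak_scale` N per kg of body mass, a monotone heel-to-toe center-of-
#' pressure progression, and additive Gaussian sensor noise. Sampling rates
#' default to 100 Hz for the on-board sensors and 200 Hz for the force
#' plate.
#'
#' @param stride_period Stride period in s (default 1.6, a comfortable slow
#'   walk).
#' @param duty_factor Stance fraction of the stride (default 0.62).
#' @param body_mass Body mass in kg.
#' @param n_strides Number of strides to generate.
#' @param fs_sensors Sampling rate of tactels and IMU in Hz (default 100).
#' @param fs_forceplate Sampling rate of the force plate in Hz (default
#'   200).
#' @param noise_sd_voltage SD of additive tactel voltage noise in V.
#' @param noise_sd_accel SD of accelerometer noise in m/s^2.
#' @param noise_sd_gyro SD of gyroscope noise in deg/s.
#' @param noise_sd_force SD of force-plate noise in N.
#' @param peak_scale Peak vertical force per unit body mass in N/kg
#'   (default 10.4).
#' @param cop_start,cop_end Center-of-pressure coordinates (cm) at stance
#'   onset and lift-off; must lie inside the layout span.
#' @param hs_impact_delay Delay in s of the accelerometer impact transient
#'   after true foot contact (default 0.02).
#' @param seed Integer seed making the trial fully reproducible.
#' @return An object of class `gait_profile_params`.
#' @export
gait_profile_params <- function(stride_period = 1.6, duty_factor = 0.62,
                                body_mass = 70, n_strides = 20,
                                fs_sensors = 100, fs_forceplate = 200,
                                noise_sd_voltage = 0.005,
                                noise_sd_accel = 0.1, noise_sd_gyro = 1,
                                noise_sd_force = 0.5, peak_scale = 10.4,
                                cop_start = 2, cop_end = 21,
                                hs_impact_delay = 0.02, seed = 1L) {
  stopifnot(stride_period > 0, duty_factor > 0, duty_factor < 1,
            body_mass > 0, n_strides >= 0, fs_sensors > 0,
            fs_forceplate > 0, noise_sd_voltage >= 0, noise_sd_accel >= 0,
            noise_sd_gyro >= 0, noise_sd_force >= 0, peak_scale > 0,
            hs_impact_delay >= 0)
  structure(list(stride_period = stride_period, duty_factor = duty_factor,
                 body_mass = body_mass, n_strides = as.integer(n_strides),
                 fs_sensors = fs_sensors, fs_forceplate = fs_forceplate,
                 noise_sd_voltage = noise_sd_voltage,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro,
                 noise_sd_force = noise_sd_force, peak_scale = peak_scale,
                 cop_start = cop_start, cop_end = cop_end,
                 hs_impact_delay = hs_impact_delay, seed = as.integer(seed)),
            class = "gait_profile_params")
}

# raised-cosine lobe with compact support [center - halfwidth, center + halfwidth]
rc_lobe <- function(t, center, halfwidth) {
  u <- (t - center) / halfwidth
  ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
}

#' Synthetic double-bump vertical ground reaction force profile
#'
#' Smooth, nonnegative stance profile built from two raised-cosine lobes
#' (weight acceptance and push-off) with a mid-stance valley; zero at the
#' contact and lift-off boundaries. The peak equals
#' `peak_scale * body_mass` N.
#'
#' @param phase Stance fraction in \[0, 1\]; vectorized.
#' @param body_mass Body mass in kg.
#' @param peak_scale Peak force per unit mass in N/kg (default 10.4).
#' @return Force(s) in N.
#' @export
synth_vgrf_profile <- function(phase, body_mass, peak_scale = 10.4) {
  phase <- as.numeric(phase)
  if (any(!is.finite(phase)) || any(phase < 0) || any(phase > 1)) {
    stop("phase must lie in [0, 1]", call. = FALSE)
  }
  peak <- peak_scale * body_mass
  peak * (rc_lobe(phase, 0.28, 0.28) + 0.95 * rc_lobe(phase, 0.72, 0.28))
}

#' Synthetic heel-to-toe center-of-pressure trajectory
#'
#' Monotone non-decreasing smoothstep progression from a heel-region
#' coordinate at contact to a forefoot-region coordinate at lift-off.
#'
#' @param phase Stance fraction in \[0, 1\]; vectorized.
#' @param y_start,y_end Coordinates (cm) at phase 0 and 1.
#' @return Position(s) in cm.
#' @export
synth_cop_trajectory <- function(phase, y_start = 2, y_end = 21) {
  phase <- as.numeric(phase)
  if (any(!is.finite(phase)) || any(phase < 0) || any(phase > 1)) {
    stop("phase must lie in [0, 1]", call. = FALSE)
  }
  s <- phase * phase * (3 - 2 * phase)
  y_start + (y_end - y_start) * s
}

#' Distribute a total force over the tactel array at a target centroid
#'
#' Produces nonnegative per-tactel forces that sum to `total_force` and
#' whose weighted centroid (the center-of-pressure estimator with the
#' layout's `wyi`) equals `cop_y` to within 1e-6 cm. Load is concentrated
#' on the tactels nearest `cop_y` through an Epanechnikov kernel of
#' configurable width, with side masses rebalanced so the centroid
#' constraint holds exactly. When `min_force > 0`, tactels whose share
#' would fall below it are dropped (and the remainder rebalanced) so every
#' emitted nonzero force stays above the voltage activity gate; exactness
#' takes precedence if the support collapses to fewer than three tactels.
#'
#' @param total_force Total vertical force in N (>= 0).
#' @param cop_y Target centroid in cm; must lie within the layout span.
#' @param layout A [tactel_layout()].
#' @param kernel_width Kernel half-width in cm (default 3).
#' @param min_force Minimum nonzero per-tactel force in N (default 0).
#' @return Numeric vector of per-tactel forces in N.
#' @export
distribute_to_tactels <- function(total_force, cop_y,
                                  layout = default_tactel_layout(),
                                  kernel_width = 3, min_force = 0) {
  yi <- layout$yi
  w <- layout$wyi
  n <- layout$count
  if (!is.finite(total_force) || total_force < 0) {
    stop("total_force must be a nonnegative force", call. = FALSE)
  }
  if (!is.finite(cop_y) || cop_y < min(yi) - 1e-9 || cop_y > max(yi) + 1e-9) {
    stop("cop_y must lie within the layout span", call. = FALSE)
  }
  f <- numeric(n)
  if (total_force == 0) return(f)

  g <- pmax(0, 1 - ((yi - cop_y) / kernel_width)^2)

  add_sides <- function(sup) {
    if (!any(yi[sup] < cop_y - 1e-12)) {
      below <- which(yi < cop_y - 1e-12)
      if (length(below)) sup <- sort(union(sup, below[which.max(yi[below])]))
    }
    if (!any(yi[sup] > cop_y + 1e-12)) {
      above <- which(yi > cop_y + 1e-12)
      if (length(above)) sup <- sort(union(sup, above[which.min(yi[above])]))
    }
    sup
  }

  # fractions over the support with exact weighted-centroid balance
  solve_frac <- function(sup) {
    gs <- g[sup]
    gmax <- max(gs, 1e-3)
    gs[gs <= 1e-12] <- 1e-3 * gmax
    mom <- w[sup] * (yi[sup] - cop_y)
    Lm <- mom < -1e-12
    Rm <- mom > 1e-12
    Zm <- !(Lm | Rm)
    SL <- sum(gs[Lm] * mom[Lm])
    SR <- sum(gs[Rm] * mom[Rm])
    fr <- numeric(length(sup))
    if (abs(SL) < 1e-14 || abs(SR) < 1e-14) {
      if (!any(Zm)) return(NULL)
      fr[Zm] <- gs[Zm]
    } else {
      a <- SR
      b <- -SL
      fr[Lm] <- a * gs[Lm]
      fr[Rm] <- b * gs[Rm]
      fr[Zm] <- 0.5 * (a + b) * gs[Zm]
    }
    fr / sum(fr)
  }

  sup <- which(g > 1e-12)
  if (!length(sup)) sup <- which.min(abs(yi - cop_y))
  # a support whose moments all vanish (e.g. a delta kernel on a tactel at
  # the target) already satisfies the centroid constraint on its own
  if (!all(abs(w[sup] * (yi[sup] - cop_y)) < 1e-12)) sup <- add_sides(sup)
  fr <- solve_frac(sup)
  if (is.null(fr)) {        # degenerate fallback: all load on nearest tactel
    f[which.min(abs(yi - cop_y))] <- total_force
    return(f)
  }
  if (min_force > 0) {
    repeat {
      forces <- total_force * fr
      viol <- which(fr > 0 & forces < min_force - 1e-12)
      if (!length(viol) || length(sup) <= 2L) break
      drop <- sup[viol[which.min(forces[viol])]]
      sup2 <- add_sides(setdiff(sup, drop))
      if (length(sup2) == length(sup) && all(sup2 == sup)) break
      fr2 <- solve_frac(sup2)
      if (is.null(fr2)) break
      sup <- sup2
      fr <- fr2
    }
  }
  f[sup] <- total_force * fr
  f
}

#' Synthetic IMU trace for a set of ground-truth events
#'
#' Deterministic (noise-free) IMU morphology consistent with the
#' finite-state machine's assumptions: for every stride, `wx` carries one
#' positive raised-cosine hump peaking at mid-swing (amplitude 150 deg/s)
#' and one negative trough centered at the true toe-off (amplitude -120
#' deg/s); `az` sits at gravity (9.81 m/s^2) with a sharp impact transient
#' (amplitude 12 m/s^2, half-width 30 ms) shortly after each true heel
#' strike; `ax` and `ay` are flat. Channel noise is added by
#' [simulate_trial()], not here.
#'
#' @param truth A [gait_events()] object with the true HS/TO times. The
#'   first heel strike should be preceded by at least half a swing so the
#'   first mid-swing hump fits in the trace.
#' @param params A [gait_profile_params()] (stride timing and rates).
#' @return An [imu_series()].
#' @export
synth_imu_trace <- function(truth, params) {
  if (!inherits(truth, "gait_events")) {
    stop("truth must be a gait_events object", call. = FALSE)
  }
  sw <- (1 - params$duty_factor) * params$stride_period
  t_end <- if (length(truth$to)) max(truth$to) + 0.35 else 1
  t <- seq(0, t_end, by = 1 / params$fs_sensors)
  wx <- numeric(length(t))
  az <- rep(9.81, length(t))
  w_msw <- 0.28 * sw
  w_to <- 0.20 * sw
  for (h in truth$hs) {
    wx <- wx + 150 * rc_lobe(t, h - sw / 2, w_msw)
    az <- az + 12 * rc_lobe(t, h + params$hs_impact_delay, 0.03)
  }
  for (o in truth$to) {
    wx <- wx - 120 * rc_lobe(t, o, w_to)
  }
  imu_series(t = t, ax = numeric(length(t)), ay = numeric(length(t)),
             az = az, wx = wx)
}

#' Simulate a complete instrumented-foot trial
#'
#' Assembles a fully seeded synthetic trial: tactel voltages (stance forces
#' distributed over the layout, converted to voltages through the inverse
#' calibration map on the negative branch, plus Gaussian noise), the IMU
#' trace of [synth_imu_trace()] plus channel noise, a force-plate vertical
#' force channel at its own rate plus noise, and the ground-truth event
#' times. The first heel strike occurs one full swing after trial start so
#' the mid-swing arming peak of the IMU detector is present for stride 1.
#'
#' @param params A [gait_profile_params()].
#' @param layout,poly,thr Sensing configuration (defaults: the reference
#'   16-tactel layout, published calibration coefficients, default gates).
#' @param branch Monotone voltage branch for the calibration inverse.
#' @return An object of class `synthetic_trial` with fields `pressure`
#'   (list `t`, `voltages`), `imu` ([imu_series()]), `fz` (list `t`, `fz`),
#'   `truth` ([gait_events()]), `params`, and `config`.
#' @export
simulate_trial <- function(params = gait_profile_params(),
                           layout = default_tactel_layout(),
                           poly = calibration_polynomial(),
                           thr = sensing_thresholds(), branch = c(-2, 0)) {
  if (!inherits(params, "gait_profile_params")) {
    stop("params must be a gait_profile_params object", call. = FALSE)
  }
  span <- range(layout$yi)
  if (params$cop_start < span[1] || params$cop_end > span[2]) {
    stop("cop trajectory endpoints must lie within the layout span",
         call. = FALSE)
  }
  set.seed(params$seed)
  T_str <- params$stride_period
  st <- params$duty_factor * T_str
  sw <- T_str - st
  hs <- sw + (seq_len(params$n_strides) - 1) * T_str
  to <- hs + st
  truth <- gait_events(hs, to)
  t_end <- if (length(to)) max(to) + 0.35 else 1
  ts <- seq(0, t_end, by = 1 / params$fs_sensors)
  tf <- seq(0, t_end, by = 1 / params$fs_forceplate)

  stance_field <- function(tt, fun) {
    out <- numeric(length(tt))
    for (k in seq_along(hs)) {
      ink <- tt >= hs[k] & tt <= to[k]
      if (any(ink)) {
        ph <- pmin(pmax((tt[ink] - hs[k]) / st, 0), 1)
        out[ink] <- fun(ph)
      }
    }
    out
  }
  vgrf_at <- function(tt) stance_field(tt, function(ph)
    synth_vgrf_profile(ph, params$body_mass, params$peak_scale))
  cop_at <- function(tt) stance_field(tt, function(ph)
    synth_cop_trajectory(ph, params$cop_start, params$cop_end))

  fz_true <- vgrf_at(tf)
  fz <- fz_true + stats::rnorm(length(tf), 0, params$noise_sd_force)

  # per-tactel forces -> voltages; forces below the gate-equivalent force
  # would be invisible to the sensing chain, so the distributor avoids them
  min_f <- force_from_voltage(thr$VT, poly) * 1.01
  tot <- vgrf_at(ts)
  cop <- cop_at(ts)
  vmat <- matrix(0, nrow = length(ts), ncol = layout$count)
  inv <- voltage_inverse(poly, branch)
  for (i in which(tot > 0)) {
    fi <- distribute_to_tactels(tot[i], cop[i], layout, min_force = min_f)
    nz <- fi > 0
    if (any(nz)) vmat[i, nz] <- inv(fi[nz])
  }
  if (params$noise_sd_voltage > 0) {
    vmat <- vmat + matrix(stats::rnorm(length(vmat), 0, params$noise_sd_voltage),
                          nrow = nrow(vmat))
  }

  imu <- synth_imu_trace(truth, params)
  nI <- length(imu$t)
  imu$ax <- imu$ax + stats::rnorm(nI, 0, params$noise_sd_accel)
  imu$ay <- imu$ay + stats::rnorm(nI, 0, params$noise_sd_accel)
  imu$az <- imu$az + stats::rnorm(nI, 0, params$noise_sd_accel)
  imu$wx <- imu$wx + stats::rnorm(nI, 0, params$noise_sd_gyro)

  structure(list(
    pressure = list(t = ts, voltages = vmat),
    imu = imu,
    fz = list(t = tf, fz = fz),
    truth = truth,
    params = params,
    config = list(layout = layout, poly = poly, thr = thr, branch = branch)
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial: %d strides, %.1f s, %d tactel frames at %g Hz, force plate at %g Hz (seed %d)\n",
    length(x$truth$hs), max(x$fz$t), nrow(x$pressure$voltages),
    x$params$fs_sensors, x$params$fs_forceplate, x$params$seed))
  invisible(x)
}

# vectorized calibration inverse: spline-free grid seed + safeguarded Newton
# polish; agrees with voltage_from_force() to < 1e-9 V on the branch
voltage_inverse <- function(poly, branch) {
  vg <- seq(branch[1], branch[2], length.out = 2001)
  Fg <- force_from_voltage(vg, poly)
  ord <- order(Fg)
  function(f) {
    v <- stats::approx(Fg[ord], vg[ord], xout = f, rule = 2)$y
    for (it in 1:8) {
      res <- force_from_voltage(v, poly) - f
      step <- res / force_dv(v, poly)
      v <- pmin(pmax(v - step, branch[1]), branch[2])
      if (max(abs(res)) < 1e-10) break
    }
    v
  }
}
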
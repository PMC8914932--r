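#' Benchmark one trial against its force-plate reference
#'
#' Reproduces the full evaluation pipeline on a single trial: runs the
#' pressure-threshold and IMU detectors, detects reference events on the
#' force-plate channel (20 N rule), pairs events and summarizes timing
#' errors and stance-duration errors, and assesses waveform agreement
#' (Pearson correlation and RMSE) of the stance-normalized vGRF and CoPy
#' estimates. Pressure voltages are low-pass filtered (zero-phase 2nd-order
#' Butterworth, `cutoff` Hz) before the waveform comparison only; the
#' event detectors run on unfiltered signals. The vGRF reference waveform
#' is the force-plate channel; the CoPy reference is the generator's
#' analytic heel-to-toe trajectory (a motion-capture CoP is not available
#' in simulation).
#'
#' @param trial A `synthetic_trial` (from [simulate_trial()] or
#'   [read_trial()]).
#' @param vGRFT Stance threshold in N for the pressure detector.
#' @param imu_thr An [imu_thresholds()].
#' @param confirm_lag Extremum confirmation lag in samples.
#' @param cutoff Low-pass cutoff in Hz for waveform preprocessing.
#' @param n_resample Samples per stance after time normalization.
#' @param max_gap Event-pairing window in s (default: half the reference
#'   stride period).
#' @return An object of class `benchmark_trial_report`: list with `events`
#'   (per detector/event timing stats), `stance` (stance-duration error
#'   stats), `waveforms` (Pearson/RMSE per variable), `peaks`
#'   (mass-normalized vGRF peaks for PS and FP), `stride_period`, counts.
#' @export
benchmark_trial <- function(trial, vGRFT = 15, imu_thr = imu_thresholds(),
                            confirm_lag = 3L, cutoff = 25,
                            n_resample = 1000L, max_gap = NULL) {
  cfg <- trial$config
  prm <- trial$params
  ts <- trial$pressure$t
  vmat <- trial$pressure$voltages
  fs <- prm$fs_sensors

  vgrf_ps <- vgrf_series(vmat, cfg$poly, cfg$layout, cfg$thr)
  detected <- list(
    PS = ps_segment(vgrf_ps, t = ts, vGRFT = vGRFT),
    IMU = imu_segment(trial$imu, imu_thr, confirm_lag)
  )
  reference <- force_plate_reference_events(trial$fz$fz, t = trial$fz$t)

  events <- data.frame()
  stance <- data.frame()
  for (d in names(detected)) {
    mm <- match_events(detected[[d]], reference, max_gap)
    for (typ in c("HS", "TO")) {
      pp <- mm$pairs[mm$pairs$type == typ, , drop = FALSE]
      if (!nrow(pp)) next
      st <- event_error_stats(pp, prm$stride_period)
      events <- rbind(events, data.frame(
        detector = d, event = typ, n = st$n, mae = st$mae, iqr = st$iqr,
        pct_late = st$pct_late, mae_pct_stride = st$mae_pct_stride,
        misses = sum(mm$misses$type == typ),
        false_alarms = sum(mm$false_alarms$type == typ),
        stringsAsFactors = FALSE))
    }
    st_err <- stance_duration_errors(mm)
    if (length(st_err)) {
      se <- event_error_stats(st_err, prm$stride_period)
      stance <- rbind(stance, data.frame(
        detector = d, n = se$n, mae = se$mae, iqr = se$iqr,
        pct_under = mean(st_err < 0), mae_pct_stride = se$mae_pct_stride,
        stringsAsFactors = FALSE))
    }
  }

  # waveform agreement over reference stance windows
  win <- stance_windows(reference)
  waveforms <- data.frame()
  peaks <- data.frame()
  if (nrow(win)) {
    vmat_f <- apply(vmat, 2L, lowpass_filter, fs = fs, cutoff = cutoff)
    vgrf_f <- vgrf_series(vmat_f, cfg$poly, cfg$layout, cfg$thr)
    copy_f <- copy_series(vmat_f, cfg$poly, cfg$layout, cfg$thr)
    cop_ref_fun <- truth_cop_fun(trial)
    nw <- nrow(win)
    a_vgrf <- b_vgrf <- a_cop <- b_cop <- matrix(NA_real_, nw, n_resample)
    for (k in seq_len(nw)) {
      a_vgrf[k, ] <- resample_stance(vgrf_f, ts, win$hs[k], win$to[k],
                                     n_resample)
      b_vgrf[k, ] <- resample_stance(trial$fz$fz, trial$fz$t, win$hs[k],
                                     win$to[k], n_resample)
      a_cop[k, ] <- resample_stance(copy_f, ts, win$hs[k], win$to[k],
                                    n_resample)
      grid <- seq(win$hs[k], win$to[k], length.out = n_resample)
      b_cop[k, ] <- cop_ref_fun(grid)
    }
    for (nm in c("vGRF", "CoPy")) {
      wa <- if (nm == "vGRF") waveform_agreement(a_vgrf, b_vgrf)
            else waveform_agreement(a_cop, b_cop)
      waveforms <- rbind(waveforms, data.frame(
        variable = nm, pearson_r = wa$pearson_r, rmse = wa$rmse,
        pearson_r_median = stats::median(wa$per_stride$pearson_r,
                                         na.rm = TRUE),
        rmse_median = stats::median(wa$per_stride$rmse, na.rm = TRUE),
        n_strides = wa$n_strides, stringsAsFactors = FALSE))
    }
    pk_ps <- peak_vgrf_normalized(a_vgrf, prm$body_mass)
    pk_fp <- peak_vgrf_normalized(b_vgrf, prm$body_mass)
    peaks <- data.frame(source = c("PS", "FP"),
                        median = c(pk_ps$median, pk_fp$median),
                        iqr = c(pk_ps$iqr, pk_fp$iqr),
                        stringsAsFactors = FALSE)
  }

  structure(list(events = events, stance = stance, waveforms = waveforms,
                 peaks = peaks, stride_period = prm$stride_period,
                 detected = detected, reference = reference),
            class = "benchmark_trial_report")
}

# stance windows (HS followed by its TO) of a gait_events object
stance_windows <- function(events) {
  hs <- events$hs
  to <- events$to
  out <- data.frame(hs = numeric(0), to = numeric(0))
  for (h in hs) {
    nxt_to <- to[to > h]
    if (!length(nxt_to)) next
    nxt_hs <- hs[hs > h]
    if (length(nxt_hs) && nxt_to[1] > nxt_hs[1]) next
    out <- rbind(out, data.frame(hs = h, to = nxt_to[1]))
  }
  out
}

# per-stride stance-duration errors (detected - reference) from a matching
stance_duration_errors <- function(mm) {
  hs <- mm$pairs[mm$pairs$type == "HS", , drop = FALSE]
  to <- mm$pairs[mm$pairs$type == "TO", , drop = FALSE]
  errs <- numeric(0)
  for (i in seq_len(nrow(hs))) {
    nxt <- to[to$t_ref > hs$t_ref[i], , drop = FALSE]
    if (!nrow(nxt)) next
    nxt_hs <- hs$t_ref[hs$t_ref > hs$t_ref[i]]
    if (length(nxt_hs) && nxt$t_ref[1] > nxt_hs[1]) next
    errs <- c(errs,
              (nxt$t_det[1] - hs$t_det[i]) - (nxt$t_ref[1] - hs$t_ref[i]))
  }
  errs
}

# analytic reference CoPy trajectory of a simulated trial as a function of
# time; phase clamped to [0, 1] outside the true stance
truth_cop_fun <- function(trial) {
  hs <- trial$truth$hs
  to <- trial$truth$to
  prm <- trial$params
  function(tt) {
    out <- rep(prm$cop_start, length(tt))
    for (k in seq_along(hs)) {
      ph <- (tt - hs[k]) / (to[k] - hs[k])
      ink <- ph >= 0 & ph <= 1
      out[ink] <- synth_cop_trajectory(ph[ink], prm$cop_start, prm$cop_end)
      out[ph > 1 & tt < c(hs, Inf)[k + 1L]] <- prm$cop_end
    }
    out
  }
}

#' Benchmark a cohort of trials
#'
#' Applies [benchmark_trial()] to each trial and groups the per-trial
#' results by taking the median across trials of every per-trial statistic
#' (each trial plays the role of one subject: individual medians first,
#' then the median of the individual results).
#'
#' @param trials List of trials (see [simulate_trial()]).
#' @param ... Passed on to [benchmark_trial()].
#' @return An object of class `benchmark_report`: list with `per_trial`
#'   (long data frames carrying a `trial` column) and `grouped` (medians
#'   across trials), plus `n_trials`.
#' @export
benchmark_cohort <- function(trials, ...) {
  reps <- lapply(trials, benchmark_trial, ...)
  bind_with_trial <- function(field) {
    do.call(rbind, lapply(seq_along(reps), function(i) {
      df <- reps[[i]][[field]]
      if (!nrow(df)) return(NULL)
      cbind(trial = i, df)
    }))
  }
  per_trial <- list(events = bind_with_trial("events"),
                    stance = bind_with_trial("stance"),
                    waveforms = bind_with_trial("waveforms"),
                    peaks = bind_with_trial("peaks"))
  med_by <- function(df, keys, vals) {
    if (is.null(df) || !nrow(df)) return(data.frame())
    agg <- stats::aggregate(df[vals], df[keys], stats::median)
    agg
  }
  grouped <- list(
    events = med_by(per_trial$events, c("detector", "event"),
                    c("mae", "iqr", "pct_late", "mae_pct_stride")),
    stance = med_by(per_trial$stance, "detector",
                    c("mae", "iqr", "pct_under", "mae_pct_stride")),
    waveforms = med_by(per_trial$waveforms, "variable",
                       c("pearson_r", "rmse")),
    peaks = med_by(per_trial$peaks, "source", c("median", "iqr"))
  )
  structure(list(per_trial = per_trial, grouped = grouped,
                 n_trials = length(reps)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report over %d trials\n", x$n_trials))
  cat("Grouped event-timing MAE (s):\n")
  print(x$grouped$events, row.names = FALSE)
  if (nrow(x$grouped$waveforms)) {
    cat("Grouped waveform agreement:\n")
    print(x$grouped$waveforms, row.names = FALSE)
  }
  invisible(x)
}
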
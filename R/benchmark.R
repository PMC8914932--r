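#' Zero-phase Butterworth low-pass filter
#'
#' Offline preprocessing of pressure/force waveforms: a 2nd-order
#' Butterworth low-pass (default cutoff 25 Hz) applied forward and backward
#' so the output is zero-phase. The real-time event detectors never use
#' this filter.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order (default 2).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 25, order = 2) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly below the Nyquist frequency",
         call. = FALSE)
  }
  x <- as.numeric(x)
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (DC gain then holds exactly on constants)
  np <- min(n - 1L, max(12L * order, ceiling(10 * fs / cutoff)))
  if (np > 0L) {
    head_pad <- 2 * x[1] - x[(np + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    as.numeric(y[(np + 1L):(np + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Resample one stance phase onto a fixed-length grid
#'
#' Linearly interpolates a time series onto `n` evenly spaced points
#' spanning \[hs, to\], the standard time normalization for comparing
#' stance waveforms across strides.
#'
#' @param x Numeric series.
#' @param t Timestamps of `x` in s.
#' @param hs,to Stance window boundaries in s (`to > hs`).
#' @param n Number of output samples (default 1000).
#' @return Numeric vector of length exactly `n`.
#' @export
resample_stance <- function(x, t, hs, to, n = 1000L) {
  if (!is.finite(hs) || !is.finite(to) || to <= hs) {
    stop("stance window must satisfy to > hs", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(t)
  if (sum(ok) < 2L) stop("stance must contain at least 2 samples",
                         call. = FALSE)
  stats::approx(t[ok], x[ok], xout = seq(hs, to, length.out = n),
                rule = 2)$y
}

# optimal monotone one-to-one matching of two sorted time lists:
# maximize the number of within-gap pairs, then minimize total |error|
match_times <- function(det, ref, max_gap) {
  nr <- length(ref)
  nd <- length(det)
  m <- matrix(0L, nr + 1L, nd + 1L)
  cost <- matrix(0, nr + 1L, nd + 1L)
  mv <- matrix(0L, nr + 1L, nd + 1L)  # 1 skip ref, 2 skip det, 3 pair
  for (i in 0:nr) {
    for (j in 0:nd) {
      if (i == 0L && j == 0L) next
      bm <- -1L; bc <- Inf; bmv <- 0L
      if (i > 0L) { bm <- m[i, j + 1L]; bc <- cost[i, j + 1L]; bmv <- 1L }
      if (j > 0L) {
        cm <- m[i + 1L, j]; cc <- cost[i + 1L, j]
        if (cm > bm || (cm == bm && cc < bc)) { bm <- cm; bc <- cc; bmv <- 2L }
      }
      if (i > 0L && j > 0L) {
        e <- abs(det[j] - ref[i])
        if (e <= max_gap) {
          cm <- m[i, j] + 1L; cc <- cost[i, j] + e
          if (cm > bm || (cm == bm && cc < bc)) { bm <- cm; bc <- cc; bmv <- 3L }
        }
      }
      m[i + 1L, j + 1L] <- bm
      cost[i + 1L, j + 1L] <- bc
      mv[i + 1L, j + 1L] <- bmv
    }
  }
  ri <- integer(0); di <- integer(0)
  i <- nr; j <- nd
  while (i > 0L || j > 0L) {
    step <- mv[i + 1L, j + 1L]
    if (step == 3L) { ri <- c(i, ri); di <- c(j, di); i <- i - 1L; j <- j - 1L }
    else if (step == 1L) i <- i - 1L
    else j <- j - 1L
  }
  list(ref_idx = ri, det_idx = di)
}

#' Pair detected events with reference events
#'
#' One-to-one pairing of each reference event with a same-type detected
#' event within `max_gap`, chosen to maximize the number of pairs and then
#' minimize the total absolute timing error (order-preserving assignment).
#' Unmatched reference events are misses; unmatched detected events are
#' false alarms.
#'
#' @param detected,reference [gait_events()] objects.
#' @param max_gap Maximum pairing distance in s. Default: half the median
#'   reference stride period (0.5 s when the reference has fewer than two
#'   heel strikes).
#' @return An object of class `event_matching`: list with `pairs` (data
#'   frame `type`, `t_ref`, `t_det`, `error` where `error = t_det - t_ref`),
#'   `misses`, and `false_alarms` (data frames `type`, `time_s`).
#' @export
match_events <- function(detected, reference, max_gap = NULL) {
  if (!inherits(detected, "gait_events") ||
      !inherits(reference, "gait_events")) {
    stop("detected and reference must be gait_events objects", call. = FALSE)
  }
  if (is.null(max_gap)) {
    max_gap <- if (length(reference$hs) >= 2L) {
      stats::median(diff(reference$hs)) / 2
    } else 0.5
  }
  pairs <- data.frame(type = character(0), t_ref = numeric(0),
                      t_det = numeric(0), error = numeric(0),
                      stringsAsFactors = FALSE)
  misses <- false_alarms <- data.frame(type = character(0),
                                       time_s = numeric(0),
                                       stringsAsFactors = FALSE)
  for (typ in c("HS", "TO")) {
    ref <- if (typ == "HS") reference$hs else reference$to
    det <- if (typ == "HS") detected$hs else detected$to
    mm <- match_times(det, ref, max_gap)
    if (length(mm$ref_idx)) {
      pairs <- rbind(pairs, data.frame(
        type = typ, t_ref = ref[mm$ref_idx], t_det = det[mm$det_idx],
        error = det[mm$det_idx] - ref[mm$ref_idx],
        stringsAsFactors = FALSE))
    }
    mi <- setdiff(seq_along(ref), mm$ref_idx)
    fa <- setdiff(seq_along(det), mm$det_idx)
    if (length(mi)) misses <- rbind(misses, data.frame(
      type = typ, time_s = ref[mi], stringsAsFactors = FALSE))
    if (length(fa)) false_alarms <- rbind(false_alarms, data.frame(
      type = typ, time_s = det[fa], stringsAsFactors = FALSE))
  }
  structure(list(pairs = pairs, misses = misses,
                 false_alarms = false_alarms, max_gap = max_gap),
            class = "event_matching")
}

#' Event-timing error statistics
#'
#' Summaries of the signed timing errors (detected minus reference) of a
#' set of matched events: the median absolute error (MAE), the
#' interquartile range of absolute errors (linear-interpolation quantiles),
#' the fraction of late detections, and the MAE as a percentage of the
#' stride period.
#'
#' @param pairs An `event_matching` object, its `pairs` data frame, or a
#'   plain numeric vector of signed errors in s.
#' @param stride_period Stride period in s used for the percentage scale.
#' @return An object of class `event_error_stats`: list with `errors`,
#'   `n`, `mae`, `iqr`, `pct_late`, `mae_pct_stride`.
#' @export
event_error_stats <- function(pairs, stride_period) {
  e <- if (inherits(pairs, "event_matching")) pairs$pairs$error
       else if (is.data.frame(pairs)) pairs$error
       else as.numeric(pairs)
  if (length(e) < 1L) stop("no matched events to summarize", call. = FALSE)
  if (!is.finite(stride_period) || stride_period <= 0) {
    stop("stride_period must be positive", call. = FALSE)
  }
  ae <- abs(e)
  q <- stats::quantile(ae, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(errors = e, n = length(e), mae = stats::median(ae),
                 iqr = q[2] - q[1], pct_late = mean(e > 0),
                 mae_pct_stride = 100 * stats::median(ae) / stride_period),
            class = "event_error_stats")
}

#' @export
print.event_error_stats <- function(x, ...) {
  cat(sprintf("MAE %.3f s (IQR %.3f s, %.2f%% of stride), %d events, %.0f%% late\n",
              x$mae, x$iqr, x$mae_pct_stride, x$n, 100 * x$pct_late))
  invisible(x)
}

#' Waveform agreement between two stance-resampled matrices
#'
#' Pearson correlation and RMSE between two sets of stance-normalized
#' waveforms (strides in rows, resampled samples in columns), pooled over
#' all samples; per-stride values are retained so medians and IQRs can be
#' reported.
#'
#' @param a,b Numeric matrices of equal shape.
#' @return An object of class `waveform_agreement`: list with `pearson_r`,
#'   `rmse`, `n_strides`, and `per_stride` (data frame `pearson_r`,
#'   `rmse`). A zero-variance input yields `NA` correlation.
#' @export
waveform_agreement <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have equal shapes",
                                   call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  safe_cor <- function(u, v) {
    if (length(u) < 2L || stats::sd(u) == 0 || stats::sd(v) == 0) {
      return(NA_real_)
    }
    stats::cor(u, v)
  }
  per <- data.frame(
    pearson_r = vapply(seq_len(nrow(a)), function(i) {
      ki <- ok[i, ]
      safe_cor(a[i, ki], b[i, ki])
    }, numeric(1)),
    rmse = vapply(seq_len(nrow(a)), function(i) {
      ki <- ok[i, ]
      sqrt(mean((a[i, ki] - b[i, ki])^2))
    }, numeric(1))
  )
  structure(list(pearson_r = safe_cor(a[ok], b[ok]),
                 rmse = sqrt(mean((a[ok] - b[ok])^2)),
                 n_strides = nrow(a), per_stride = per),
            class = "waveform_agreement")
}

#' Body-mass-normalized per-stride vGRF peaks
#'
#' @param vgrf_stances Matrix of stance-resampled vertical force waveforms
#'   (strides in rows) or a single numeric waveform, in N.
#' @param body_mass Body mass in kg (> 0).
#' @return List with `peaks` (per-stride peaks in N/kg), `median`, `iqr`.
#' @export
peak_vgrf_normalized <- function(vgrf_stances, body_mass) {
  if (!is.finite(body_mass) || body_mass <= 0) {
    stop("body_mass must be positive", call. = FALSE)
  }
  m <- if (is.matrix(vgrf_stances)) vgrf_stances else
    matrix(vgrf_stances, nrow = 1L)
  peaks <- apply(m, 1L, max, na.rm = TRUE) / body_mass
  q <- stats::quantile(peaks, c(0.25, 0.75), names = FALSE, type = 7)
  list(peaks = peaks, median = stats::median(peaks), iqr = q[2] - q[1])
}
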
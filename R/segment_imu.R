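#' IMU time series of the prosthetic foot
#'
#' Uniformly sampled accelerations (m/s^2) and sagittal angular velocity
#' (deg/s) from the foot-mounted IMU. Sign convention: positive `wx` is the
#' swing-phase rotation, so the mid-swing peak is positive and the pre-toe-
#' off trough negative. Accelerations are raw accelerometer output (gravity
#' included on the vertical channel).
#'
#' @param t Timestamps in s (strictly increasing, uniformly spaced), or
#'   `NULL` to build them from `fs`.
#' @param ax,ay,az Accelerations along the IMU axes in m/s^2.
#' @param wx Angular velocity about the IMU x-axis (sagittal plane) in
#'   deg/s.
#' @param fs Sampling rate in Hz (required when `t` is `NULL`).
#' @return An object of class `imu_series` with fields `t`, `ax`, `ay`,
#'   `az`, `wx`, `fs`.
#' @export
imu_series <- function(t = NULL, ax, ay, az, wx, fs = NULL) {
  n <- length(wx)
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("all IMU channels must have the same length", call. = FALSE)
  }
  if (n < 2L) stop("IMU series needs at least two samples", call. = FALSE)
  t <- resolve_time(t, fs, n)
  fs <- 1 / mean(diff(t))
  structure(list(t = t, ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), wx = as.numeric(wx), fs = fs),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("IMU series: %d samples at %.6g Hz (%.2f s)\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Thresholds of the IMU finite-state machine
#'
#' @param wxT_MSw Mid-swing angular-velocity threshold in deg/s (default
#'   75): a confirmed local maximum of `wx` at or above it arms the
#'   heel-strike search.
#' @param wxT_TO Toe-off angular-velocity threshold in deg/s (default -65):
#'   a confirmed local minimum of `wx` at or below it marks toe-off.
#' @param aT Acceleration threshold in m/s^2 (default 7): minimum
#'   peak-to-peak excursion of at least one acceleration channel in the
#'   window before an `az` peak for it to count as the heel-strike impact.
#' @param hs_search_window Maximum time in s after mid-swing to find the
#'   heel strike (default 0.75); on expiry the machine re-arms.
#' @param idle_after_hs Idle period in s after a heel strike before the
#'   toe-off search starts (default 0.4).
#' @param pre_peak_window Length in s of the pre-peak acceleration window
#'   (default 0.030).
#' @return An object of class `imu_thresholds`.
#' @export
imu_thresholds <- function(wxT_MSw = 75, wxT_TO = -65, aT = 7,
                           hs_search_window = 0.75, idle_after_hs = 0.4,
                           pre_peak_window = 0.030) {
  if (!(wxT_MSw > 0 && wxT_TO < 0)) {
    stop("require wxT_MSw > 0 > wxT_TO", call. = FALSE)
  }
  if (any(c(hs_search_window, idle_after_hs, pre_peak_window) <= 0)) {
    stop("all FSM windows must be positive", call. = FALSE)
  }
  structure(list(wxT_MSw = wxT_MSw, wxT_TO = wxT_TO, aT = aT,
                 hs_search_window = hs_search_window,
                 idle_after_hs = idle_after_hs,
                 pre_peak_window = pre_peak_window),
            class = "imu_thresholds")
}

#' IMU finite-state-machine gait segmentation
#'
#' Causal single-pass detector cycling through the states
#' `WAIT_MSW -> SEARCH_HS -> IDLE -> SEARCH_TO -> WAIT_MSW`:
#' \enumerate{
#'   \item In `WAIT_MSW`, a confirmed local maximum of `wx` at or above
#'     `wxT_MSw` marks mid-swing and arms the heel-strike search.
#'   \item In `SEARCH_HS`, the heel strike is the time of a confirmed local
#'     maximum of `az` such that, within `pre_peak_window` before that
#'     maximum, at least one of `ax`, `ay`, `az` spans a peak-to-peak range
#'     of at least `aT`. If no heel strike occurs within
#'     `hs_search_window` of mid-swing, the machine returns to `WAIT_MSW`.
#'   \item After a heel strike the machine idles for `idle_after_hs`
#'     (timer anchored at the event timestamp).
#'   \item In `SEARCH_TO`, the toe-off is the time of a confirmed local
#'     minimum of `wx` at or below `wxT_TO`, after which the machine
#'     re-arms.
#' }
#' Extrema are confirmed `confirm_lag` samples after they occur
#' (see [confirm_local_extremum()]); emitted timestamps are the extremum
#' times themselves.
#'
#' @param imu An [imu_series()].
#' @param thr An [imu_thresholds()].
#' @param confirm_lag Confirmation lag in samples (default 3, i.e. 30 ms at
#'   100 Hz).
#' @return A [gait_events()] object.
#' @export
imu_segment <- function(imu, thr = imu_thresholds(), confirm_lag = 3L) {
  if (!inherits(imu, "imu_series")) {
    stop("imu must be an imu_series", call. = FALSE)
  }
  if (!inherits(thr, "imu_thresholds")) {
    stop("thr must be an imu_thresholds object", call. = FALSE)
  }
  confirm_lag <- as.integer(confirm_lag)
  if (confirm_lag < 1L) stop("confirm_lag must be >= 1", call. = FALSE)
  t <- imu$t
  n <- length(t)
  fs <- imu$fs
  # samples inside (t_peak - pre_peak_window, t_peak]
  win_n <- floor(thr$pre_peak_window * fs - 1e-9) + 1L
  if (win_n < 2L) {
    stop("sampling rate too low to resolve the pre-peak window (needs >= 2 samples)",
         call. = FALSE)
  }
  acc <- cbind(imu$ax, imu$ay, imu$az)
  hs <- numeric(0)
  to <- numeric(0)
  state <- "WAIT_MSW"
  msw_t <- NA_real_
  hs_t <- NA_real_

  for (j in seq_len(n)) {
    cand <- j - confirm_lag
    if (cand <= confirm_lag) next
    tc <- t[cand]
    # timeout and idle-expiry edges are evaluated before the candidate
    if (state == "SEARCH_HS" && tc > msw_t + thr$hs_search_window) {
      state <- "WAIT_MSW"
    }
    if (state == "IDLE" && tc >= hs_t + thr$idle_after_hs) {
      state <- "SEARCH_TO"
    }
    if (state == "WAIT_MSW") {
      if (imu$wx[cand] >= thr$wxT_MSw &&
          confirm_local_extremum(imu$wx, cand, "max", confirm_lag)$confirmed) {
        msw_t <- tc
        state <- "SEARCH_HS"
      }
    } else if (state == "SEARCH_HS") {
      if (confirm_local_extremum(imu$az, cand, "max", confirm_lag)$confirmed) {
        k0 <- max(1L, cand - win_n + 1L)
        p2p <- apply(acc[k0:cand, , drop = FALSE], 2L,
                     function(a) diff(range(a)))
        if (max(p2p) >= thr$aT) {
          hs <- c(hs, tc)
          hs_t <- tc
          state <- "IDLE"
        }
      }
    } else if (state == "SEARCH_TO") {
      if (imu$wx[cand] <= thr$wxT_TO &&
          confirm_local_extremum(imu$wx, cand, "min", confirm_lag)$confirmed) {
        to <- c(to, tc)
        state <- "WAIT_MSW"
      }
    }
  }
  gait_events(hs = hs, to = to)
}
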
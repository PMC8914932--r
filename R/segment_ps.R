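#' Pressure-threshold gait segmentation
#'
#' Classifies each sample as stance (vertical force at or above `vGRFT`) or
#' swing, and emits a heel strike at every swing-to-stance transition and a
#' toe-off at every stance-to-swing transition. Event timestamps are
#' assigned to the first sample of the new phase (no sub-sample
#' interpolation). A trial that starts or ends mid-phase produces no event
#' for the partial boundary phases.
#'
#' @param vgrf Numeric vertical force series in N, uniformly sampled.
#' @param t Timestamps in s (same length as `vgrf`); alternatively give
#'   `fs`.
#' @param fs Sampling rate in Hz, used to build timestamps from 0 when `t`
#'   is missing.
#' @param vGRFT Stance threshold in N. Values outside the tuning range
#'   \[10, 20\] N trigger a warning.
#' @return A [gait_events()] object.
#' @export
ps_segment <- function(vgrf, t = NULL, fs = NULL, vGRFT = 15) {
  vgrf <- as.numeric(vgrf)
  if (length(vgrf) == 0L) stop("empty force series", call. = FALSE)
  if (any(!is.finite(vgrf))) stop("force series must be finite", call. = FALSE)
  t <- resolve_time(t, fs, length(vgrf))
  if (!is.finite(vGRFT) || vGRFT <= 0) {
    stop("vGRFT must be positive", call. = FALSE)
  }
  if (vGRFT < 10 || vGRFT > 20) {
    warning(sprintf("vGRFT = %g N is outside the tuning range [10, 20] N",
                    vGRFT), call. = FALSE)
  }
  stance <- vgrf >= vGRFT
  d <- diff(stance)
  gait_events(hs = t[which(d == 1L) + 1L], to = t[which(d == -1L) + 1L])
}

#' Force-plate reference events
#'
#' Reference segmentation of a force-plate vertical force trace with the
#' conventional 20 N contact threshold; contract otherwise identical to
#' [ps_segment()].
#'
#' @param fz Force-plate vertical force series in N.
#' @inheritParams ps_segment
#' @return A [gait_events()] object.
#' @export
force_plate_reference_events <- function(fz, t = NULL, fs = NULL) {
  ps_segment(fz, t = t, fs = fs, vGRFT = 20)
}

resolve_time <- function(t, fs, n) {
  if (!is.null(t)) {
    t <- as.numeric(t)
    if (length(t) != n) stop("t must match the series length", call. = FALSE)
    if (n > 1L) {
      dt <- diff(t)
      if (any(dt <= 0)) stop("timestamps must be strictly increasing",
                             call. = FALSE)
      if (max(dt) - min(dt) > 1e-9 * max(dt)) {
        stop("timestamps must be uniformly spaced", call. = FALSE)
      }
    }
    return(t)
  }
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    stop("provide timestamps t or a positive sampling rate fs", call. = FALSE)
  }
  seq(0, by = 1 / fs, length.out = n)
}
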
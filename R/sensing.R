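#' A single pressure frame
#'
#' One time sample of per-tactel output voltages.
#'
#' @param voltages Numeric vector, one voltage (V) per tactel.
#' @param timestamp Time of the sample in seconds (optional).
#' @return An object of class `pressure_frame`.
#' @export
pressure_frame <- function(voltages, timestamp = NA_real_) {
  voltages <- as.numeric(voltages)
  if (length(voltages) == 0L || any(!is.finite(voltages))) {
    stop("voltages must be finite numeric", call. = FALSE)
  }
  structure(list(voltages = voltages, timestamp = as.numeric(timestamp)),
            class = "pressure_frame")
}

frame_voltages <- function(frame, layout) {
  v <- if (inherits(frame, "pressure_frame")) frame$voltages else as.numeric(frame)
  if (length(v) != layout$count) {
    stop(sprintf("frame has %d voltages but layout has %d tactels",
                 length(v), layout$count), call. = FALSE)
  }
  v
}

# gated, clamped per-tactel forces for one frame (vector of N, zeros where
# the tactel is inactive, i.e. voltage above the VT gate)
tactel_forces <- function(v, poly, layout, thr) {
  active <- v <= thr$VT
  f <- numeric(length(v))
  if (any(active)) {
    f[active] <- pmax(force_from_voltage(v[active], poly), 0)
  }
  f
}

#' Vertical ground reaction force from one pressure frame
#'
#' Sums the calibrated force of every active tactel. A tactel is active when
#' its voltage is at or below the gate `thr$VT` (pressed tactels output
#' negative voltage); inactive tactels contribute 0 N. Negative calibrated
#' forces (possible for very small deflections) are clamped to 0 N, and the
#' total is clamped to be nonnegative.
#'
#' @param frame A [pressure_frame()] or a plain voltage vector.
#' @param poly A [calibration_polynomial()].
#' @param layout A [tactel_layout()].
#' @param thr A [sensing_thresholds()].
#' @return Total vertical force in N.
#' @export
compute_vgrf <- function(frame, poly = calibration_polynomial(),
                         layout = default_tactel_layout(),
                         thr = sensing_thresholds()) {
  v <- frame_voltages(frame, layout)
  max(sum(tactel_forces(v, poly, layout, thr)), 0)
}

#' Longitudinal center of pressure from one pressure frame
#'
#' When the foot is loaded (vertical force at or above `thr$vGRFT`) returns
#' the force-weighted mean tactel coordinate
#' \eqn{\sum F_i w_{yi} y_i / \sum F_i w_{yi}} in cm from the heel;
#' otherwise returns `NA_real_` (the undefined marker for an unloaded foot).
#'
#' @inheritParams compute_vgrf
#' @return Position in cm, or `NA_real_` when the foot is not loaded.
#' @export
compute_copy <- function(frame, poly = calibration_polynomial(),
                         layout = default_tactel_layout(),
                         thr = sensing_thresholds()) {
  v <- frame_voltages(frame, layout)
  f <- tactel_forces(v, poly, layout, thr)
  if (sum(f) < thr$vGRFT) return(NA_real_)
  den <- sum(f * layout$wyi)
  if (den <= 0) {
    stop("foot is loaded but all center-of-pressure weights vanish",
         call. = FALSE)
  }
  sum(f * layout$wyi * layout$yi) / den
}

#' Vectorized vGRF and CoPy over a voltage time series
#'
#' Applies the frame-wise estimators of [compute_vgrf()] and
#' [compute_copy()] to every row of a voltage matrix.
#'
#' @param vmat Numeric matrix, samples in rows, one column per tactel.
#' @inheritParams compute_vgrf
#' @return `vgrf_series()`: numeric vector of forces (N). `copy_series()`:
#'   numeric vector of positions (cm) with `NA` where the foot is unloaded.
#' @export
vgrf_series <- function(vmat, poly = calibration_polynomial(),
                        layout = default_tactel_layout(),
                        thr = sensing_thresholds()) {
  fmat <- force_matrix(vmat, poly, layout, thr)
  pmax(rowSums(fmat), 0)
}

#' @rdname vgrf_series
#' @export
copy_series <- function(vmat, poly = calibration_polynomial(),
                        layout = default_tactel_layout(),
                        thr = sensing_thresholds()) {
  fmat <- force_matrix(vmat, poly, layout, thr)
  vgrf <- pmax(rowSums(fmat), 0)
  num <- as.numeric(fmat %*% (layout$wyi * layout$yi))
  den <- as.numeric(fmat %*% layout$wyi)
  out <- rep(NA_real_, length(vgrf))
  ok <- vgrf >= thr$vGRFT & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

force_matrix <- function(vmat, poly, layout, thr) {
  vmat <- as.matrix(vmat)
  if (ncol(vmat) != layout$count) {
    stop(sprintf("voltage matrix has %d columns but layout has %d tactels",
                 ncol(vmat), layout$count), call. = FALSE)
  }
  f <- ((((poly$p1 * vmat + poly$p2) * vmat + poly$p3) * vmat + poly$p4) *
          vmat) + poly$p5
  f[vmat > thr$VT] <- 0
  f[f < 0] <- 0
  f
}
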
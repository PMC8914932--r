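#' Voltage-to-force calibration polynomial for an optoelectronic tactel
#'
#' Each pressure-sensitive element (tactel) couples an LED/photodiode pair to
#' a deformable silicone pad: normal force lowers an internal curtain that
#' obstructs the light path, so the photodiode output voltage encodes the
#' applied force. Bench characterization yields a quartic map
#' \eqn{F(V) = p_1 V^4 + p_2 V^3 + p_3 V^2 + p_4 V + p_5} (force in N,
#' voltage in V). The defaults are the published coefficients of the
#' instrumented foot; with them \eqn{F(0) = 0} and pressed tactels output
#' negative voltages on a strictly monotone branch.
#'
#' @param p1,p2,p3,p4,p5 Polynomial coefficients, quartic term first.
#' @return An object of class `calibration_polynomial`.
#' @examples
#' poly <- calibration_polynomial()
#' force_from_voltage(-1, poly)  # 44.95 N
#' @export
calibration_polynomial <- function(p1 = 186.1, p2 = 224.5, p3 = 64.76,
                                   p4 = -18.59, p5 = 0) {
  p <- c(p1, p2, p3, p4, p5)
  if (!is.numeric(p) || length(p) != 5L || !all(is.finite(p))) {
    stop("calibration coefficients must be five finite numbers", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5),
            class = "calibration_polynomial")
}

#' @export
print.calibration_polynomial <- function(x, ...) {
  cat("Tactel calibration polynomial F(V) [N]:\n")
  cat(sprintf("  %g V^4 + %g V^3 + %g V^2 + %g V + %g\n",
              x$p1, x$p2, x$p3, x$p4, x$p5))
  invisible(x)
}

#' Convert a tactel voltage to force
#'
#' Evaluates the quartic calibration map in nested (Horner) form. Vectorized
#' over `v`.
#'
#' @param v Voltage(s) in V; must be finite.
#' @param poly A [calibration_polynomial()].
#' @return Force(s) in N.
#' @export
force_from_voltage <- function(v, poly = calibration_polynomial()) {
  if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v))) {
    stop("voltage must be finite numeric", call. = FALSE)
  }
  ((((poly$p1 * v + poly$p2) * v + poly$p3) * v + poly$p4) * v) + poly$p5
}

# derivative of the calibration map, used for branch monotonicity checks
force_dv <- function(v, poly) {
  ((4 * poly$p1 * v + 3 * poly$p2) * v + 2 * poly$p3) * v + poly$p4
}

# TRUE when the map is strictly monotone over [branch[1], branch[2]]
branch_is_monotone <- function(poly, branch, n_grid = 512L) {
  vg <- seq(branch[1], branch[2], length.out = n_grid)
  dF <- force_dv(vg, poly)
  all(dF < 0) || all(dF > 0)
}

#' Invert the calibration map on a monotone voltage branch
#'
#' Finds the voltage producing a requested force with a bracketing
#' root-finder. Pressed tactels output negative voltages, so the simulator
#' uses the negative branch (default `c(-2, 0)`), on which the published
#' coefficients are strictly decreasing in voltage (force grows as voltage
#' becomes more negative). Vectorized over `f`.
#'
#' @param f Force(s) in N; must lie in the image of the branch.
#' @param poly A [calibration_polynomial()].
#' @param branch Length-2 voltage interval on which the map is strictly
#'   monotone.
#' @param tol Root-finder tolerance on voltage.
#' @return Voltage(s) in V such that `force_from_voltage(v)` reproduces `f`
#'   to well within 1e-6 N.
#' @export
voltage_from_force <- function(f, poly = calibration_polynomial(),
                               branch = c(-2, 0), tol = 1e-12) {
  if (!is.numeric(f) || any(!is.finite(f))) {
    stop("force must be finite numeric", call. = FALSE)
  }
  branch <- sort(as.numeric(branch))
  if (!branch_is_monotone(poly, branch)) {
    stop("calibration polynomial is not strictly monotone on the requested branch",
         call. = FALSE)
  }
  f_lo <- force_from_voltage(branch[1], poly)
  f_hi <- force_from_voltage(branch[2], poly)
  rng <- sort(c(f_lo, f_hi))
  if (any(f < rng[1] - 1e-9) || any(f > rng[2] + 1e-9)) {
    stop(sprintf("force outside image [%.6g, %.6g] N of the branch",
                 rng[1], rng[2]), call. = FALSE)
  }
  vapply(f, function(fi) {
    if (fi <= rng[1]) return(if (f_lo <= f_hi) branch[1] else branch[2])
    if (fi >= rng[2]) return(if (f_lo <= f_hi) branch[2] else branch[1])
    stats::uniroot(function(v) force_from_voltage(v, poly) - fi,
                   interval = branch, tol = tol)$root
  }, numeric(1))
}
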
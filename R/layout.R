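#' Tactel layout of the instrumented foot sole
#'
#' Describes where each pressure-sensitive element sits along the
#' longitudinal (heel to toe) axis of the prosthetic foot, its anatomical
#' region, and its center-of-pressure weight. The reference design
#' instruments 16 tactels -- 5 under the heel and 11 under the forefoot --
#' whose coordinates span 0 to 22.8 cm from the heel.
#'
#' @param yi Numeric vector of per-tactel longitudinal coordinates (cm from
#'   the heel).
#' @param region Character vector, one of `"heel"` or `"forefoot"` per
#'   tactel.
#' @param wyi Nonnegative per-tactel center-of-pressure weights. The lever
#'   arm is already carried by `yi`, so the default weight is 1 for every
#'   tactel.
#' @return An object of class `tactel_layout` with fields `count`, `yi`,
#'   `region`, `wyi`.
#' @seealso [default_tactel_layout()]
#' @export
tactel_layout <- function(yi, region, wyi = rep(1, length(yi))) {
  yi <- as.numeric(yi)
  wyi <- as.numeric(wyi)
  region <- as.character(region)
  if (length(yi) < 1L || any(!is.finite(yi))) {
    stop("yi must be finite coordinates", call. = FALSE)
  }
  if (length(region) != length(yi) || !all(region %in% c("heel", "forefoot"))) {
    stop("region must label each tactel as 'heel' or 'forefoot'", call. = FALSE)
  }
  if (length(wyi) != length(yi) || any(!is.finite(wyi)) || any(wyi < 0) ||
      !any(wyi > 0)) {
    stop("wyi must be nonnegative with at least one positive weight",
         call. = FALSE)
  }
  structure(list(count = length(yi), yi = yi, region = region, wyi = wyi),
            class = "tactel_layout")
}

#' Default 16-tactel layout (5 heel + 11 forefoot)
#'
#' Heel tactels are placed uniformly on \[0, 6\] cm and forefoot tactels
#' uniformly on \[12, 22.8\] cm; only the 0--22.8 cm span and the 5/11 split
#' are constrained by the reference design, so individual coordinates are a
#' declared convention (also shipped in the bundled JSON config).
#'
#' @return A `tactel_layout` with 16 tactels.
#' @export
default_tactel_layout <- function() {
  tactel_layout(
    yi = c(seq(0, 6, length.out = 5), seq(12, 22.8, length.out = 11)),
    region = c(rep("heel", 5), rep("forefoot", 11))
  )
}

#' @export
print.tactel_layout <- function(x, ...) {
  cat(sprintf("Tactel layout: %d tactels (%d heel, %d forefoot), span [%g, %g] cm\n",
              x$count, sum(x$region == "heel"), sum(x$region == "forefoot"),
              min(x$yi), max(x$yi)))
  invisible(x)
}

#' Sensing thresholds for pressure processing
#'
#' `VT` is the per-tactel voltage activity gate: a tactel contributes to the
#' vertical ground reaction force only when its output is at or below `VT`
#' (pressed tactels output negative voltage), which keeps zero-mean noise on
#' unpressed tactels out of the force sum. `vGRFT` is the minimum vertical
#' force (N) for the foot to count as loaded: it defines stance for the
#' pressure-threshold event detector and the validity region of the center
#' of pressure. The detector is tuned within \[10, 20\] N.
#'
#' @param VT Voltage gate in V (default -0.05 V).
#' @param vGRFT Minimum vertical force in N (default 15 N); must be > 0.
#' @return An object of class `sensing_thresholds`.
#' @export
sensing_thresholds <- function(VT = -0.05, vGRFT = 15) {
  if (!is.finite(VT)) stop("VT must be finite", call. = FALSE)
  if (!is.finite(vGRFT) || vGRFT <= 0) {
    stop("vGRFT must be a positive force in N", call. = FALSE)
  }
  structure(list(VT = VT, vGRFT = vGRFT), class = "sensing_thresholds")
}
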
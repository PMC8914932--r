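#' Ordered gait events
#'
#' Heel-strike (HS) and toe-off (TO) timestamps of one trial. Each list is
#' strictly increasing and, merged in time, the event types must alternate
#' (HS, TO, HS, ...): between two consecutive heel strikes there is exactly
#' one toe-off. A trial that starts mid-stance may legitimately begin with a
#' TO.
#'
#' @param hs Strictly increasing heel-strike times (s).
#' @param to Strictly increasing toe-off times (s).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(hs = numeric(), to = numeric()) {
  hs <- as.numeric(hs)
  to <- as.numeric(to)
  if (any(!is.finite(hs)) || any(!is.finite(to))) {
    stop("event times must be finite", call. = FALSE)
  }
  if (is.unsorted(hs, strictly = TRUE) || is.unsorted(to, strictly = TRUE)) {
    stop("event times must be strictly increasing within each type",
         call. = FALSE)
  }
  typ <- c(rep("HS", length(hs)), rep("TO", length(to)))
  tt <- c(hs, to)
  typ <- typ[order(tt)]
  if (length(typ) > 1L && any(typ[-1] == typ[-length(typ)])) {
    stop("HS and TO events must alternate in time", call. = FALSE)
  }
  structure(list(hs = hs, to = to), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d HS, %d TO", length(x$hs), length(x$to)))
  if (length(x$hs)) cat(sprintf(" (first HS %.3f s, last HS %.3f s)",
                                x$hs[1], x$hs[length(x$hs)]))
  cat("\n")
  invisible(x)
}

#' Per-stride stance durations
#'
#' For each heel strike followed by a toe-off (before the next heel strike)
#' returns the elapsed time TO - HS. A trailing heel strike without a
#' closing toe-off is omitted.
#'
#' @param events A [gait_events()] object.
#' @return Numeric vector of stance durations in s.
#' @export
stance_durations <- function(events) {
  if (!inherits(events, "gait_events")) {
    stop("events must be a gait_events object", call. = FALSE)
  }
  hs <- events$hs
  to <- events$to
  out <- numeric(0)
  for (h in hs) {
    nxt_to <- to[to > h]
    if (!length(nxt_to)) next
    nxt_hs <- hs[hs > h]
    if (length(nxt_hs) && nxt_to[1] > nxt_hs[1]) next
    out <- c(out, nxt_to[1] - h)
  }
  out
}

#' Convert gait events to a data frame
#'
#' @param x A [gait_events()] object.
#' @param detector Detector label to attach (`"PS"`, `"IMU"`, `"FP"`, ...).
#' @param ... Unused.
#' @return A data frame with columns `event_type`, `time_s`, `detector`,
#'   ordered by time.
#' @export
as.data.frame.gait_events <- function(x, detector = NA_character_, ...) {
  df <- data.frame(
    event_type = c(rep("HS", length(x$hs)), rep("TO", length(x$to))),
    time_s = c(x$hs, x$to),
    detector = detector,
    stringsAsFactors = FALSE
  )
  df[order(df$time_s), , drop = FALSE]
}
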
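#' Causal confirmation of a local extremum
#'
#' A streaming detector cannot call a sample a local maximum until enough
#' later samples have arrived. Sample `i` is a confirmed extremum when it is
#' strictly more extreme than its `confirm_lag` predecessors and at least as
#' extreme as its `confirm_lag` successors; on a flat plateau the extremum is
#' assigned to the earliest plateau sample. The event timestamp is the time
#' of sample `i`, but it only becomes known `confirm_lag` samples later
#' (the confirmation index `i + confirm_lag`).
#'
#' @param x Numeric time series.
#' @param i Sample index to test.
#' @param mode `"max"` or `"min"`.
#' @param confirm_lag Number of samples on each side required to confirm
#'   (>= 1).
#' @return A list with `confirmed` (logical), `index` (`i`), and
#'   `confirm_index` (`i + confirm_lag`, `NA` when the window does not fit).
#' @export
confirm_local_extremum <- function(x, i, mode = c("max", "min"),
                                   confirm_lag = 1L) {
  mode <- match.arg(mode)
  confirm_lag <- as.integer(confirm_lag)
  if (confirm_lag < 1L) stop("confirm_lag must be >= 1", call. = FALSE)
  n <- length(x)
  if (i < 1L || i > n) stop("index out of range", call. = FALSE)
  if (i - confirm_lag < 1L || i + confirm_lag > n) {
    return(list(confirmed = FALSE, index = i, confirm_index = NA_integer_))
  }
  s <- if (mode == "max") 1 else -1
  xi <- s * x[i]
  pred <- s * x[(i - confirm_lag):(i - 1L)]
  succ <- s * x[(i + 1L):(i + confirm_lag)]
  ok <- all(xi > pred) && all(xi >= succ)
  list(confirmed = ok, index = i, confirm_index = i + confirm_lag)
}

#' Indices of all confirmed extrema of a series
#'
#' Offline convenience wrapper scanning every interior sample with
#' [confirm_local_extremum()].
#'
#' @inheritParams confirm_local_extremum
#' @return Integer vector of confirmed extremum indices.
#' @export
confirmed_extrema <- function(x, mode = c("max", "min"), confirm_lag = 1L) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 2L * confirm_lag + 1L) return(integer(0))
  idx <- (confirm_lag + 1L):(n - confirm_lag)
  idx[vapply(idx, function(i) {
    confirm_local_extremum(x, i, mode, confirm_lag)$confirmed
  }, logical(1))]
}
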
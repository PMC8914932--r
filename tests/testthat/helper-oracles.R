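# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation paths: term-by-term sums, brute-force loops,
# hand-written quantile/correlation formulas.

# term-by-term quartic evaluation (no Horner nesting)
oracle_poly <- function(v, p) {
  p[1] * v^4 + p[2] * v^3 + p[3] * v^2 + p[4] * v + p[5]
}

# brute-force weighted-mean center of pressure over gated, clamped forces
oracle_copy <- function(voltages, p, yi, wyi, VT) {
  num <- 0
  den <- 0
  for (i in seq_along(voltages)) {
    if (voltages[i] <= VT) {
      fi <- max(oracle_poly(voltages[i], p), 0)
      num <- num + fi * wyi[i] * yi[i]
      den <- den + fi * wyi[i]
    }
  }
  num / den
}

# sort-and-interpolate quantile (type-7 convention, written from the
# textbook formula)
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# direct-formula Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# offline strict local extrema of a series (interior points with the full
# confirmation window), for tie-free inputs
oracle_extrema <- function(x, mode, lag) {
  s <- if (mode == "max") 1 else -1
  out <- integer(0)
  for (i in (lag + 1):(length(x) - lag)) {
    win_prev <- s * x[(i - lag):(i - 1)]
    win_next <- s * x[(i + 1):(i + lag)]
    if (all(s * x[i] > win_prev) && all(s * x[i] > win_next)) {
      out <- c(out, i)
    }
  }
  out
}

# exhaustive one-to-one event pairing: maximize matches, then minimize the
# total absolute error, over all injective assignments within the gap
oracle_match <- function(det, ref, max_gap) {
  best <- list(m = -1L, cost = Inf)
  nd <- length(det)
  assign_next <- function(i, used, m, cost) {
    if (i > length(ref)) {
      if (m > best$m || (m == best$m && cost < best$cost)) {
        best <<- list(m = m, cost = cost)
      }
      return(invisible())
    }
    assign_next(i + 1, used, m, cost)  # leave ref i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && abs(det[j] - ref[i]) <= max_gap) {
        used[j] <- TRUE
        assign_next(i + 1, used, m + 1L, cost + abs(det[j] - ref[i]))
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, logical(nd), 0L, 0)
  best
}

# canonical single-stride IMU trace: mid-swing hump, impact burst, toe-off
# trough, at configurable offsets from the hump peak
canonical_stride_imu <- function(fs = 100, msw_t = 1, hs_offset = 0.2,
                                 to_offset = 0.8, t_end = 3) {
  t <- seq(0, t_end, by = 1 / fs)
  lobe <- function(t, c, w) ifelse(abs(t - c) < w,
                                   0.5 * (1 + cos(pi * (t - c) / w)), 0)
  wx <- 150 * lobe(t, msw_t, 0.15) - 120 * lobe(t, msw_t + to_offset, 0.1)
  az <- 9.81 + 12 * lobe(t, msw_t + hs_offset, 0.03)
  imu_series(t = t, ax = numeric(length(t)), ay = numeric(length(t)),
             az = az, wx = wx)
}

default_poly_coefs <- c(186.1, 224.5, 64.76, -18.59, 0)
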
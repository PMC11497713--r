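# Independent oracles, coded separately from the package internals.

# Natural cubic spline through (x, y): second derivatives from the standard
# tridiagonal system (zero curvature at the ends), solved directly.
natural_spline_oracle <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  function(t) {
    vapply(t, function(ti) {
      i <- findInterval(ti, x, rightmost.closed = TRUE)
      i <- min(max(i, 1), n - 1)
      hi <- h[i]
      a <- (x[i + 1] - ti) / hi
      bb <- (ti - x[i]) / hi
      M[i] * (x[i + 1] - ti)^3 / (6 * hi) + M[i + 1] * (ti - x[i])^3 / (6 * hi) +
        (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - ti) +
        (y[i + 1] / hi - M[i + 1] * hi / 6) * (ti - x[i])
    }, numeric(1))
  }
}

# Closed-form cumulative delay of the linear-in-treated-time fading rule:
# the rate falls linearly from s at T_end to 0 at T16, so the integral from
# T_end to t is s * (t - T_end) * (T16 - (t + T_end)/2) / (T16 - T_end).
fading_delay_oracle <- function(t, s, T_end, T16, d_end = s * T_end) {
  tt <- pmin(t, T16)
  d_end + s * (tt - T_end) * (T16 - (tt + T_end) / 2) / (T16 - T_end)
}

# Self-consistent fading milestone time: active reaches the milestone when
# t - delay(t) equals the placebo milestone time T_p.
fading_milestone_oracle <- function(T_p, s, T_end, d_end = s * T_end) {
  (T_p + d_end - s * T_end / 2) / (1 - s / 2)
}

fixture_traj <- function() generate_fixture_trajectory()
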
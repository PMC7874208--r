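# Independent brute-force oracles: deliberately naive implementations used
# only to check the package's vectorized/library-backed code paths.

# Sort-based centered windowed median with symmetric shrink at the edges.
oracle_rolling_median <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1, n - i)
    w <- sort(x[(i - k):(i + k)])
    out[i] <- w[(length(w) + 1) %/% 2]   # odd-length window: middle element
  }
  out
}

oracle_difference <- function(x, window, valid = rep(TRUE, length(x))) {
  med <- oracle_rolling_median(x, window)
  d <- numeric(length(x))
  for (i in seq_along(x)) {
    d[i] <- if (valid[i]) abs(x[i] - med[i]) else 0
  }
  d
}

# Per-frame accumulation of the four cycle metrics, no shortcuts. Values
# are collected frame by frame and summed once at the end, so the result is
# bitwise comparable with any left-to-right summation of the same frames.
oracle_cycle_metrics <- function(x, valid, start0, end0, threshold, window) {
  d <- oracle_difference(x, window, valid)
  mx <- -Inf; vals <- numeric(0); nab <- 0L
  for (f in (start0 + 1):end0) {        # 1-based frames of [start0, end0)
    if (!valid[f]) next
    vals <- c(vals, d[f])
    if (d[f] > mx) mx <- d[f]
    if (d[f] > threshold) nab <- nab + 1L
  }
  data.frame(max_tail_angle = mx, normalized_integral = sum(vals) / length(vals),
             pct_above_threshold = 100 * nab / length(vals),
             active = mx > threshold)
}

# Literal step-up definition: q(i) = min over j >= i of m * p(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Step-by-step resource recursion: continuous depletion per stimulated
# cycle, bouts fire (deterministically when prob = 1) above threshold.
# Returns resource before each cycle and the fired flags/amplitudes.
oracle_resource <- function(pool_init, delta, threshold, n_cycles,
                            bout_amplitude = 30, adaptation = 0) {
  R <- pool_init
  res <- data.frame(resource = numeric(n_cycles), fired = logical(n_cycles),
                    amplitude = numeric(n_cycles))
  for (i in seq_len(n_cycles)) {
    res$resource[i] <- R
    if (R >= threshold) {
      res$fired[i] <- TRUE
      res$amplitude[i] <- bout_amplitude * R * (1 - adaptation)^(i - 1)
    }
    R <- max(0, R - delta)
  }
  res
}

# Independent plain-loop implementation of the half-time definition.
oracle_half_time <- function(v, tmid) {
  n <- length(v)
  B <- mean(v[1:3])
  sm <- numeric(n)
  for (i in seq_len(n)) sm[i] <- mean(v[max(1, i - 1):min(n, i + 1)])
  for (i in seq_len(n - 1)) {
    if (sm[i] <= B / 2 && sm[i + 1] <= B / 2) {
      if (i == 1 || sm[i - 1] <= B / 2) return(tmid[max(i - 1, 1)])
      f <- (sm[i - 1] - B / 2) / (sm[i - 1] - sm[i])
      return(tmid[i - 1] + f * (tmid[i] - tmid[i - 1]))
    }
  }
  NA_real_
}
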
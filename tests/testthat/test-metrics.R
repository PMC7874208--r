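test_that("rolling median handles constants, outliers and edge shrink", {
  expect_equal(rolling_median(rep(3.5, 20), 5), rep(3.5, 20))
  expect_equal(rolling_median(c(0, 0, 10, 0, 0), 5)[3], 0)
  expect_error(rolling_median(1:10, 4), "odd")
  expect_error(rolling_median(1:3, 5), "odd integer between")
  # shrinking edge windows: first value is its own median, second is median of 3
  x <- c(5, 1, 9, 2, 7, 3)
  expect_equal(rolling_median(x, 5)[1], 5)
  expect_equal(rolling_median(x, 5)[2], stats::median(x[1:3]))
})

test_that("rolling median equals the brute-force sort-based oracle", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(200, sd = 10)
    for (w in c(3, 5, 9)) {
      expect_identical(rolling_median(x, w), oracle_rolling_median(x, w))
    }
  }
})

test_that("difference signal isolates fast deviations from slow sway", {
  expect_equal(difference_signal(rep(2, 50)), rep(0, 50))
  x <- numeric(51); x[26] <- 12
  expect_equal(difference_signal(x)[26], 12)
  expect_equal(sum(difference_signal(x)[-26]), 0)
  # slow sinusoid: bounded by the per-window curvature of the sway
  t <- (0:999) / 30
  sway <- 8 * sin(2 * pi * 0.53 * t)
  bound <- 8 * (2 * pi * 0.53 / 30)^2 * 4   # generous curvature bound
  expect_lt(max(difference_signal(sway)), bound)
  # invalid frames are zeroed
  v <- rep(TRUE, 51); v[26] <- FALSE
  expect_equal(difference_signal(x, valid = v)[26], 0)
})

test_that("segmentation of the standard recording retains 21 cycles", {
  tr <- simulate_trace(phenotype_wildtype(startle_rate = 0), stimulus_protocol(),
                       seed = 1)
  cyc <- segment_cycles(tr)
  expect_identical(nrow(cyc), 23L)
  expect_identical(sum(!cyc$excluded), 21L)
  expect_identical(cyc$exclusion_reason[1], "first")
  expect_identical(cyc$exclusion_reason[23], "last_or_partial")
  expect_true(cyc$partial[23])        # 1280 - 22 * 56 = 48 < 56 frames
  # retained spans tile the interval between the excluded edges
  ret <- cyc[!cyc$excluded, ]
  expect_identical(ret$start[-1], ret$end[-nrow(ret)])
  expect_true(all(ret$end > ret$start))
})

test_that("degenerate segmentations behave as specified", {
  expect_error(segment_cycles(manual_trace(rnorm(50), black = 10)), "2 black")
  # two markers: first cycle and trailing remainder both excluded -> 0 retained
  tr <- manual_trace(rnorm(100), black = c(0, 40))
  cyc <- segment_cycles(tr)
  expect_identical(sum(!cyc$excluded), 0L)
  # five equal cycles, no partial remainder -> cycles 1..3 retained
  tr5 <- spike_trace(rep(10, 5))
  cyc5 <- segment_cycles(tr5)
  expect_identical(nrow(cyc5), 5L)
  expect_identical(cyc5$cycle_index[!cyc5$excluded], 1:3)
})

test_that("startle exclusion applies the 45-degree rule to retained cycles", {
  tr <- spike_trace(c(10, 50, 44.9, 10, 10, 10))
  cyc <- flag_startles(tr, segment_cycles(tr))
  expect_identical(cyc$exclusion_reason[2], "startle")
  expect_false(cyc$excluded[3])       # 44.9 stays below the bound
  # simulated recording with exactly one injected startle
  p <- stimulus_protocol()
  par <- phenotype_wildtype(startle_rate = 0)
  tr2 <- simulate_trace(par, p, seed = 4)
  base <- segment_cycles(tr2)
  pick <- base[!base$excluded, ][10, ]
  tr2$angles[pick$start + 25 + 1] <- tr2$angles[pick$start + 25 + 1] + 80
  cyc2 <- flag_startles(tr2, base)
  expect_identical(sum(cyc2$exclusion_reason == "startle"), 1L)
  expect_identical(cyc2$cycle_index[cyc2$exclusion_reason == "startle"],
                   pick$cycle_index)
})

test_that("cycle metrics match hand arithmetic on a constructed cycle", {
  # 56 valid frames, difference exactly 8 on 14 isolated frames, 0 elsewhere
  ang <- numeric(56)
  ang[2 + 4 * (0:13)] <- 8
  tr <- tail_trace(ang, fps = 30)
  cycle <- data.frame(cycle_index = 0L, start = 0L, end = 56L)
  m <- cycle_metrics(tr, cycle)
  expect_equal(m$max_tail_angle, 8)
  expect_equal(m$normalized_integral, 2)       # 8 * 14 / 56
  expect_equal(m$pct_above_threshold, 25)      # 100 * 14 / 56
  expect_true(m$active)
  # constant-zero difference -> all metrics zero, inactive
  tr0 <- tail_trace(rep(1.5, 56), fps = 30)
  m0 <- cycle_metrics(tr0, cycle)
  expect_equal(unlist(m0[1:3]), c(max_tail_angle = 0, normalized_integral = 0,
                                  pct_above_threshold = 0))
  expect_false(m0$active)
  # frames at exactly the threshold do not count as above it
  ang5 <- numeric(56); ang5[c(10, 20, 30)] <- 5
  m5 <- cycle_metrics(tail_trace(ang5, fps = 30), cycle)
  expect_equal(m5$pct_above_threshold, 0)
  expect_false(m5$active)
  # cycle with no valid frames is degenerate
  trb <- tail_trace(rep(1, 56), fps = 30, black_frames = 0:55)
  expect_error(cycle_metrics(trb, cycle), "degenerate")
})

test_that("metric invariants hold and match the brute-force oracle", {
  p <- short_protocol()
  for (s in 1:10) {
    tr <- simulate_trace(phenotype_wildtype(startle_rate = 0.05), p, seed = s)
    m <- cycle_metrics_table(tr)
    ret <- m[!m$excluded, ]
    expect_true(all(ret$normalized_integral_deg <= ret$max_tail_angle_deg + 1e-12))
    expect_true(all(ret$max_tail_angle_deg <= 45))
    expect_true(all(ret$pct_above_threshold >= 0 & ret$pct_above_threshold <= 100))
    # pct above threshold is non-increasing in the threshold
    m10 <- cycle_metrics_table(tr, threshold = 10)
    expect_true(all(m10$pct_above_threshold[!m10$excluded] <=
                      ret$pct_above_threshold + 1e-12))
    # exact agreement with the per-frame brute-force implementation
    for (i in which(!m$excluded)) {
      o <- oracle_cycle_metrics(tr$angles, tr$valid, m$start[i], m$end[i],
                                threshold = 5, window = 5)
      expect_identical(m$max_tail_angle_deg[i], o$max_tail_angle)
      expect_identical(m$normalized_integral_deg[i], o$normalized_integral)
      expect_identical(m$pct_above_threshold[i], o$pct_above_threshold)
    }
  }
})
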
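test_that("half-time handles sustained, step and degenerate responses", {
  d <- 56 / 30
  tmid <- (0:6) * d + d / 2
  # constant response never halves
  expect_true(is.na(half_time(rep(4, 7), tmid)))
  # step response B,B,B,0,0,0,0: hand interpolation places the crossing at 3d
  B <- 6
  expect_equal(half_time(c(B, B, B, 0, 0, 0, 0), tmid), 3 * d)
  # agreement with the independent plain-loop implementation on random series
  set.seed(3)
  for (i in 1:50) {
    v <- abs(rnorm(21, mean = 3, sd = 2)) * exp(-(0:20) / runif(1, 2, 30))
    expect_equal(half_time(v, (0:20) * d + d / 2), oracle_half_time(v, (0:20) * d + d / 2))
  }
  expect_error(half_time(c(0, 0, 0, 0), tmid[1:4]), "no initial response")
  expect_error(half_time(c(1, 2, 3), tmid[1:3]), ">= 4")
})

test_that("half-time tracks the depletion recursion in simulated mutants", {
  p <- stimulus_protocol()
  d <- 56 / 30
  par <- phenotype_synj1(depletion_per_cycle = 0.3, bout_prob = 1,
                         startle_rate = 0, response_threshold = 0.2)
  tr <- simulate_trace(par, p, seed = 6)
  trial <- summarize_trial(tr, p)
  # prediction: per-cycle response proportional to the fired amplitude of
  # the resource recursion over the 21 retained cycles (global cycles 1..21)
  rec <- oracle_resource(1, 0.3, 0.2, 23)
  pred <- oracle_half_time(rec$amplitude[2:22], trial$per_cycle$time_mid_s)
  expect_lt(abs(trial$half_time_s - pred), d)
})

test_that("half-time is non-increasing in the depletion rate", {
  p <- stimulus_protocol()
  # restricted to depletion rates at which the first three retained cycles
  # still fire, so the half-time baseline reflects evoked signal
  ht <- vapply(c(0.1, 0.15, 0.2, 0.25), function(delta) {
    par <- phenotype_synj1(depletion_per_cycle = delta, bout_prob = 1,
                           startle_rate = 0)
    summarize_trial(simulate_trace(par, p, seed = 31), p)$half_time_s
  }, numeric(1))
  expect_false(anyNA(ht))
  expect_true(all(diff(ht) <= 1e-9))
})

test_that("pauses are maximal runs of at least two inactive cycles", {
  d <- 2
  expect_identical(pauses(rep(TRUE, 10), d), numeric(0))
  expect_equal(pauses(c(TRUE, FALSE, FALSE, FALSE, TRUE), d), 3 * d)
  expect_equal(pauses(rep(FALSE, 7), d), 7 * d)
  # a single skipped cycle is not a pause
  expect_identical(pauses(c(TRUE, FALSE, TRUE, TRUE), d), numeric(0))
  expect_equal(pauses(c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE), d), c(2, 3) * d)
})

test_that("percentage of active cycles is plain arithmetic", {
  expect_equal(pct_active(rep(TRUE, 8)), 100)
  expect_equal(pct_active(rep(FALSE, 8)), 0)
  expect_equal(round(pct_active(c(rep(TRUE, 14), rep(FALSE, 7))), 2), 66.67)
  expect_error(pct_active(logical(0)), "degenerate")
})

test_that("minimal recovery interval enumerates resumed epochs", {
  mk <- function(active_by_epoch) {
    do.call(rbind, lapply(seq_along(active_by_epoch), function(e) {
      a <- active_by_epoch[[e]]
      data.frame(epoch = e, excluded = FALSE, active = a)
    }))
  }
  rests <- c(20, 15, 10, 5, 0)
  # sustained activity in every epoch -> no recovery time needed
  always <- mk(replicate(6, rep(TRUE, 5), simplify = FALSE))
  expect_equal(min_recovery_interval(always, rests), 0)
  # activity resumes only after the 20 s and 15 s rests -> minimum is 15
  lost <- c(rep(TRUE, 2), rep(FALSE, 3))
  resumed <- mk(list(lost, lost, lost, rep(FALSE, 5), rep(FALSE, 5), rep(FALSE, 5)))
  expect_equal(min_recovery_interval(resumed, rests), 15)
  # activity lost and never resumed -> absent
  never <- mk(c(list(lost), replicate(5, rep(FALSE, 5), simplify = FALSE)))
  expect_true(is.na(min_recovery_interval(never, rests)))
  expect_error(min_recovery_interval(always, c(NA, 15, 10, 5, 0)), "rest")
  expect_error(min_recovery_interval(mk(list(rep(TRUE, 5))), rests), "2 epochs")
})

test_that("trial summaries satisfy the pause-duration budget", {
  p <- protocol_prolonged(total_s = 126)   # shorter prolonged trial
  d <- 56 / 30
  for (s in 1:5) {
    trial <- summarize_trial(simulate_trace(phenotype_synj1(), p, seed = s), p)
    expect_lte(sum(trial$pauses_s), trial$n_retained * d + 1e-9)
    expect_true(all(trial$pauses_s > 0))
  }
})

test_that("synj1-like defaults reproduce the fatigue triad", {
  p <- stimulus_protocol()
  d <- 56 / 30
  wt <- summarize_trial(simulate_trace(phenotype_wildtype(), p, seed = 17), p)
  sj <- summarize_trial(simulate_trace(phenotype_synj1(), p, seed = 17), p)
  # initial cycles active, overall activity below wild type, a long pause
  expect_true(all(sj$per_cycle$active[1:2]))
  expect_lt(sj$pct_active, wt$pct_active)
  expect_gte(max(c(0, sj$pauses_s)), 3 * d)
})

test_that("trial JSON round-trips the summary fields", {
  p <- stimulus_protocol()
  trial <- summarize_trial(simulate_trace(phenotype_synj1(), p, seed = 2), p)
  f <- withr::local_tempfile(fileext = ".json")
  write_trial_json(trial, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$pct_active, trial$pct_active)
  expect_equal(js$n_retained, trial$n_retained)
  expect_equal(unlist(js$pauses_s), trial$pauses_s)
})
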
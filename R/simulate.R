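# Tail-beat carrier frequency of evoked bouts (Hz). Tail beats are fast
# relative to the 30 fps camera, so a bout appears as a rapidly alternating
# deflection under a half-sine envelope; the 5-frame rolling median then
# tracks only the slow platform sway, as the metric definitions require.
.BEAT_HZ <- 10

#' Simulate a tail-angle trace for one larva
#'
#' Generates a seeded synthetic recording with the statistical structure the
#' analysis assumes: a slow sinusoidal sway baseline phase-locked to the
#' stimulus, stimulus-evoked tail bouts drawn from the resource-pool model of
#' [phenotype_params()], rare spontaneous startle excursions exceeding 45
#' degrees, Gaussian frame noise, and an all-black marker frame at the start
#' of every stimulus cycle.
#'
#' Per stimulated cycle, with resource `R` (initially `pool_init`):
#' a bout fires with probability `bout_prob` if `R >= response_threshold`,
#' with peak amplitude `bout_amplitude_deg * R * (1 - adaptation_rate)^k` for
#' cycle number `k`; the cycle then depletes `R <- max(0, R - delta)`
#' (stimulation is continuously depleting, whether or not a bout fired).
#' Across a rest of `dt` seconds, `R <- 1 - (1 - R) * exp(-dt / tau_rec)`.
#' A bout is a 6-12 frame half-sine envelope on a ~10 Hz alternating carrier
#' placed at a random position inside the cycle; startles use the same shape
#' with peak amplitude 60-110 degrees.
#'
#' Identical `(params, protocol, seed)` yield bit-identical traces.
#'
#' @param params A [phenotype_params()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer RNG seed; defaults to `params$seed`.
#' @return A [tail_trace()] whose `meta` records the parameters, seed and
#'   per-cycle ground truth (`meta$cycles`: resource before each cycle,
#'   whether a bout or startle was injected, and the bout amplitude).
#' @export
simulate_trace <- function(params, protocol, seed = params$seed) {
  stopifnot(inherits(params, "vsr_phenotype"), inherits(protocol, "vsr_protocol"))
  stim <- make_stimulus(protocol)
  n <- length(stim$time_s)
  fps <- protocol$fps
  cyc <- stim$cycles
  ncyc <- nrow(cyc)

  set.seed(as.integer(seed))
  angles <- params$sway_amplitude_deg *
    sin(2 * pi * protocol$frequency * stim$epoch_time_s) +
    stats::rnorm(n, 0, params$noise_sd_deg)

  # Fixed number of uniform draws per cycle, consumed whether or not the
  # corresponding event fires: keeps traces comparable across parameter
  # values under a common seed (common random numbers).
  U <- matrix(stats::runif(ncyc * 7L), nrow = ncyc, ncol = 7L)

  R <- params$pool_init
  delta <- params$depletion_per_cycle
  tau <- params$recovery_tau_s
  rests <- protocol$epochs$rest_s

  gt <- data.frame(cycle = seq_len(ncyc) - 1L, epoch = cyc$epoch,
                   resource = NA_real_, bout = FALSE, startle = FALSE,
                   bout_amplitude_deg = 0)

  inject <- function(angles, start, len_cycle, bout_len, u_pos, phase, amp) {
    # place the bout strictly inside the cycle, after the marker frame
    bout_len <- min(bout_len, len_cycle - 1L)
    pos <- 1L + floor(u_pos * (len_cycle - bout_len))   # offset within cycle
    k <- seq_len(bout_len) - 1L
    env <- sin(pi * k / max(bout_len - 1L, 1L))
    carrier <- cos(2 * pi * .BEAT_HZ * k / fps + phase)
    idx <- start + pos + k + 1L                          # 1-based frame index
    angles[idx] <- angles[idx] + amp * env * carrier
    angles
  }

  for (i in seq_len(ncyc)) {
    if (i > 1L && cyc$epoch[i] != cyc$epoch[i - 1L]) {
      dt <- rests[cyc$epoch[i - 1L]]
      if (dt > 0) {
        R <- if (tau == 0) 1 else 1 - (1 - R) * exp(-dt / tau)
      }
    }
    gt$resource[i] <- R
    len_cycle <- cyc$end[i] - cyc$start[i]
    fires <- U[i, 1L] < params$bout_prob && R >= params$response_threshold &&
      params$bout_amplitude_deg > 0
    if (fires) {
      amp <- params$bout_amplitude_deg * R *
        (1 - params$adaptation_rate)^(i - 1L)
      bout_len <- 6L + as.integer(floor(U[i, 3L] * 7))   # 6..12 frames
      angles <- inject(angles, cyc$start[i], len_cycle, bout_len,
                       U[i, 4L], 2 * pi * U[i, 5L], amp)
      gt$bout[i] <- TRUE
      gt$bout_amplitude_deg[i] <- amp
    }
    if (U[i, 2L] < params$startle_rate) {
      s_amp <- 60 + 50 * U[i, 6L]
      s_len <- 6L + as.integer(floor(U[i, 7L] * 7))
      angles <- inject(angles, cyc$start[i], len_cycle, s_len,
                       U[i, 4L], 2 * pi * U[i, 5L], s_amp)
      gt$startle[i] <- TRUE
    }
    R <- max(0, R - delta)
  }

  tail_trace(angles = angles, fps = fps, black_frames = stim$black_frames,
             time_s = stim$time_s, epoch = stim$epoch,
             meta = list(params = params, seed = as.integer(seed),
                         protocol = protocol, cycles = gt))
}

#' Simulate a cohort of larvae
#'
#' Convenience wrapper generating one trace per larva with per-larva seeds
#' derived deterministically from a base seed.
#'
#' @param params A [phenotype_params()].
#' @param protocol A [stimulus_protocol()].
#' @param n Number of larvae.
#' @param base_seed Base RNG seed; larva `i` uses `base_seed + i - 1`.
#' @param genotype Genotype label stored in each trace's `meta`.
#' @return A list of [tail_trace()] objects named `<genotype>_<i>`.
#' @export
simulate_cohort <- function(params, protocol, n, base_seed = params$seed,
                            genotype = "wildtype") {
  traces <- lapply(seq_len(n), function(i) {
    tr <- simulate_trace(params, protocol, seed = base_seed + i - 1L)
    tr$meta$genotype <- genotype
    tr$meta$larva_id <- sprintf("%s_%02d", genotype, i)
    tr
  })
  names(traces) <- vapply(traces, function(tr) tr$meta$larva_id, character(1))
  traces
}
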
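#' Half-time of the decline in reflex activity
#'
#' Time at which the per-cycle normalized-integral response first falls to
#' half its initial level. The baseline `B` is the mean normalized integral
#' of the first 3 retained cycles; the per-cycle series is smoothed with a
#' centered 3-cycle moving average (shrinking at the edges); the half-time
#' is the time, linearly interpolated between cycle midpoints, at which the
#' smoothed series first reaches `<= B/2` and remains `<= B/2` for the next
#' cycle as well.
#'
#' @param integral Normalized integrals of the retained cycles, in cycle
#'   order (degrees).
#' @param time_mid_s Midpoint times of those cycles (s).
#' @return Half-time in seconds, or `NA_real_` if the response never halves
#'   in a sustained way.
#' @export
half_time <- function(integral, time_mid_s) {
  n <- length(integral)
  if (n < 4L || length(time_mid_s) != n) {
    stop("half_time needs >= 4 retained cycles with matching times", call. = FALSE)
  }
  B <- mean(integral[1:3])
  if (B <= 0) {
    stop("undefined half-time: no initial response (baseline is 0)", call. = FALSE)
  }
  # centered 3-cycle moving average, shrinking to the available cycles
  sm <- vapply(seq_len(n), function(i) {
    mean(integral[max(1L, i - 1L):min(n, i + 1L)])
  }, numeric(1))
  half <- B / 2
  hit <- which(sm[-n] <= half & sm[-1L] <= half)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(time_mid_s[1L])
  # interpolate the crossing between the last supra-half midpoint and i
  t0 <- time_mid_s[i - 1L]; t1 <- time_mid_s[i]
  s0 <- sm[i - 1L]; s1 <- sm[i]
  if (s0 <= half) return(t0)            # already at/below half before i
  t0 + (s0 - half) / (s0 - s1) * (t1 - t0)
}

#' Pause durations in reflex activity
#'
#' A pause is a maximal run of at least 2 consecutive inactive retained
#' cycles; its duration is the run length times the cycle duration. Rest
#' periods between stimulation epochs neither break a run nor add to its
#' duration, so retained cycles are treated as one contiguous sequence.
#'
#' @param active Logical activity flags of the retained cycles, in order.
#' @param cycle_duration_s Duration of one stimulus cycle (s).
#' @param min_run Minimal run length counting as a pause, default 2.
#' @return Numeric vector of pause durations (s); empty if none.
#' @export
pauses <- function(active, cycle_duration_s, min_run = 2L) {
  stopifnot(is.logical(active), cycle_duration_s > 0)
  if (!length(active)) return(numeric(0))
  r <- rle(!active)
  lens <- r$lengths[r$values & r$lengths >= min_run]
  as.numeric(lens) * cycle_duration_s
}

#' Percentage of active cycles
#'
#' @param active Logical activity flags of the retained cycles.
#' @return `100 * sum(active) / length(active)`.
#' @export
pct_active <- function(active) {
  if (!length(active)) {
    stop("degenerate trial: no retained cycles", call. = FALSE)
  }
  100 * sum(active) / length(active)
}

#' Minimal rest interval restoring reflex activity
#'
#' For a defined-interval protocol (stimulation epochs separated by known
#' rests), an epoch is said to have *resumed* when it contains at least one
#' active cycle while the final 3 retained cycles of the preceding epoch
#' were all inactive (activity had been lost). The minimal recovery interval
#' is the shortest rest preceding any resumed epoch. Larvae that never lose
#' activity (no epoch ends with 3 inactive cycles) require no recovery time
#' and report 0; larvae that lose activity and never resume report
#' `NA_real_`.
#'
#' @param metrics Per-cycle metric table from [cycle_metrics_table()]
#'   covering all epochs (only retained cycles are used).
#' @param rest_s Rest duration after each epoch, seconds
#'   (`rest_s[e]` separates epoch `e` from epoch `e + 1`); typically
#'   `protocol$epochs$rest_s`.
#' @return Minimal recovery interval in seconds, 0, or `NA_real_`.
#' @export
min_recovery_interval <- function(metrics, rest_s) {
  ret <- metrics[!metrics$excluded, , drop = FALSE]
  epochs <- sort(unique(ret$epoch))
  if (length(epochs) < 2L) {
    stop("min_recovery_interval needs a protocol with >= 2 epochs", call. = FALSE)
  }
  if (length(rest_s) < max(epochs) - 1L || any(!is.finite(rest_s))) {
    stop("undefined rest durations for the interval protocol", call. = FALSE)
  }
  lost_after <- vapply(epochs, function(e) {
    a <- ret$active[ret$epoch == e]
    length(a) >= 3L && !any(utils::tail(a, 3L))
  }, logical(1))
  if (!any(lost_after)) return(0)
  resumed_rests <- numeric(0)
  for (k in seq_along(epochs)[-1L]) {
    e <- epochs[k]; prev <- epochs[k - 1L]
    if (lost_after[k - 1L] && any(ret$active[ret$epoch == e])) {
      resumed_rests <- c(resumed_rests, rest_s[prev])
    }
  }
  if (!length(resumed_rests)) return(NA_real_)
  min(resumed_rests)
}

#' Trial-level temporal summary of one larva
#'
#' Combines the per-cycle metric table with the temporal statistics:
#' half-time of the decline, percentage of active cycles, pause durations,
#' and (for multi-epoch protocols) the minimal recovery interval.
#'
#' @param trace A [tail_trace()].
#' @param protocol The [stimulus_protocol()] the trace was recorded under
#'   (defaults to the one stored in the trace's `meta`).
#' @param threshold Activity threshold in degrees, default 5.
#' @param window Rolling-median window, default 5.
#' @param startle_threshold Startle exclusion bound, default 45.
#' @return An object of class `vsr_trial`: a list with `per_cycle` (metric
#'   table of retained cycles with midpoint times), `half_time_s`,
#'   `pct_active`, `pauses_s`, `min_recovery_interval_s` (`NULL` for
#'   single-epoch protocols), `n_retained`, `n_excluded_startle`,
#'   `larva_id` and `genotype`.
#' @export
summarize_trial <- function(trace, protocol = trace$meta$protocol,
                            threshold = 5, window = 5L,
                            startle_threshold = 45) {
  stopifnot(inherits(trace, "vsr_trace"))
  if (is.null(protocol)) {
    stop("summarize_trial needs the stimulus protocol", call. = FALSE)
  }
  metrics <- cycle_metrics_table(trace, threshold, window, startle_threshold)
  ret <- metrics[!metrics$excluded, , drop = FALSE]
  cyc_dur <- frames_per_cycle(protocol) / protocol$fps
  ret$time_mid_s <- ret$start_time_s + cyc_dur / 2

  ht <- if (nrow(ret) >= 4L && mean(ret$normalized_integral_deg[1:3]) > 0) {
    half_time(ret$normalized_integral_deg, ret$time_mid_s)
  } else {
    NA_real_
  }
  mri <- if (nrow(protocol$epochs) >= 2L) {
    min_recovery_interval(metrics, protocol$epochs$rest_s)
  } else {
    NULL
  }
  structure(
    list(larva_id = if (!is.null(trace$meta$larva_id)) trace$meta$larva_id else "larva",
         genotype = if (!is.null(trace$meta$genotype)) trace$meta$genotype else NA_character_,
         per_cycle = ret,
         half_time_s = ht,
         pct_active = pct_active(ret$active),
         pauses_s = pauses(ret$active, cyc_dur),
         min_recovery_interval_s = mri,
         n_retained = nrow(ret),
         n_excluded_startle = sum(metrics$exclusion_reason == "startle")),
    class = "vsr_trial"
  )
}

#' @export
print.vsr_trial <- function(x, ...) {
  cat(sprintf("VSR trial %s (%s): %d retained cycles, %.1f%% active\n",
              x$larva_id, x$genotype, x$n_retained, x$pct_active))
  cat(sprintf("  half-time: %s s, pauses: %d, startle exclusions: %d\n",
              format(x$half_time_s, digits = 3), length(x$pauses_s),
              x$n_excluded_startle))
  if (!is.null(x$min_recovery_interval_s)) {
    cat("  minimal recovery interval:",
        format(x$min_recovery_interval_s, digits = 3), "s\n")
  }
  invisible(x)
}

#' Write a trial summary as JSON
#'
#' @param trial A `vsr_trial` from [summarize_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  stopifnot(inherits(trial, "vsr_trial"))
  out <- list(larva_id = trial$larva_id, genotype = trial$genotype,
              half_time_s = trial$half_time_s, pct_active = trial$pct_active,
              pauses_s = trial$pauses_s,
              min_recovery_interval_s = trial$min_recovery_interval_s,
              n_retained = trial$n_retained,
              n_excluded_startle = trial$n_excluded_startle)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
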
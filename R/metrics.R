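#' Centered rolling median of a tail-angle series
#'
#' The median of `window` neighboring tail angles (default 5), taken to
#' represent the non-evoked swaying of the tail produced by gravity and
#' liquid movement in the mounting chamber. At the series edges the window
#' shrinks symmetrically to the frames available, so the output has the same
#' length as the input.
#'
#' @param angles Numeric series (degrees).
#' @param window Odd window length, `1 <= window <= length(angles)`.
#' @return Numeric series of the same length.
#' @export
rolling_median <- function(angles, window = 5L) {
  n <- length(angles)
  if (!is.numeric(window) || length(window) != 1L || window %% 2 != 1 ||
      window < 1 || window > n) {
    stop("`window` must be an odd integer between 1 and length(angles)",
         call. = FALSE)
  }
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(angles))
  h <- (window - 1L) %/% 2L
  out <- as.numeric(stats::runmed(angles, window, endrule = "keep"))
  for (i in seq_len(h)) {            # shrink the window symmetrically
    k <- i - 1L
    out[i] <- stats::median(angles[seq.int(i - k, i + k)])
    j <- n - i + 1L
    out[j] <- stats::median(angles[seq.int(j - k, j + k)])
  }
  out
}

#' Difference signal: deviation of the tail angle from its rolling median
#'
#' `|angle - rolling_median(angle)|` per frame; every per-cycle metric is
#' computed from this nonnegative series. Invalid frames (black marker
#' frames, tracking failures) carry the value 0.
#'
#' @param angles Numeric series (degrees) or a [tail_trace()].
#' @param window Rolling-median window (odd), default 5.
#' @param valid Optional logical vector; frames marked `FALSE` are zeroed.
#'   Taken from the trace when `angles` is a `vsr_trace`.
#' @return Nonnegative numeric series of the same length.
#' @export
difference_signal <- function(angles, window = 5L, valid = NULL) {
  if (inherits(angles, "vsr_trace")) {
    valid <- angles$valid
    angles <- angles$angles
  }
  d <- abs(angles - rolling_median(angles, window))
  if (!is.null(valid)) d[!valid] <- 0
  d
}

#' Segment a trace into marker-delimited stimulus cycles
#'
#' Cycles are the half-open frame spans `[b_i, b_{i+1})` between consecutive
#' black frames within one epoch. A trailing segment after an epoch's final
#' black frame is attached as a final (partial, if shorter than the modal
#' cycle length) cycle. Within each epoch the first cycle and the final
#' complete-or-partial cycle are excluded from analysis (the recording edges
#' are unreliable), so the default 1280-frame recording with markers every
#' 56 frames yields exactly 21 retained cycles.
#'
#' @param trace A [tail_trace()] with at least 2 black frames.
#' @return A data frame with one row per cycle: `cycle_index` (0-based),
#'   `epoch`, `start`, `end` (0-based half-open frame span), `start_time_s`,
#'   `partial`, `excluded` and `exclusion_reason`
#'   (`"first"`, `"last_or_partial"` or `"none"`).
#' @export
segment_cycles <- function(trace) {
  stopifnot(inherits(trace, "vsr_trace"))
  if (length(trace$black_frames) < 2L) {
    stop("cannot segment: need at least 2 black frames", call. = FALSE)
  }
  n <- length(trace$angles)
  epochs <- sort(unique(trace$epoch))
  rows <- list()
  for (e in epochs) {
    fr <- which(trace$epoch == e) - 1L             # 0-based frames of epoch
    lo <- min(fr); hi <- max(fr) + 1L              # epoch span [lo, hi)
    b <- trace$black_frames[trace$black_frames >= lo & trace$black_frames < hi]
    if (length(b) < 2L) next
    starts <- b
    ends <- c(b[-1L], hi)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    len <- ends - starts
    modal <- as.numeric(names(which.max(table(len))))
    partial <- len < modal
    excl <- rep("none", length(starts))
    excl[1L] <- "first"
    excl[length(excl)] <- "last_or_partial"
    rows[[length(rows) + 1L]] <- data.frame(
      epoch = e, start = starts, end = ends,
      partial = partial, exclusion_reason = excl)
  }
  if (!length(rows)) {
    stop("cannot segment: no epoch contains 2 black frames", call. = FALSE)
  }
  cycles <- do.call(rbind, rows)
  cycles$cycle_index <- seq_len(nrow(cycles)) - 1L
  cycles$start_time_s <- trace$time_s[cycles$start + 1L]
  cycles$excluded <- cycles$exclusion_reason != "none"
  cycles[, c("cycle_index", "epoch", "start", "end", "start_time_s",
             "partial", "excluded", "exclusion_reason")]
}

#' Exclude cycles containing startle excursions
#'
#' Any retained cycle whose difference signal exceeds `startle_threshold`
#' (default 45 degrees; normal evoked VSR movements stay within 0-45
#' degrees, startles can exceed 100) at any frame is marked excluded with
#' reason `"startle"`.
#'
#' @param trace A [tail_trace()].
#' @param cycles Cycle table from [segment_cycles()].
#' @param startle_threshold Exclusion bound in degrees, default 45.
#' @param window Rolling-median window used for the difference signal.
#' @return The cycle table with startle exclusions applied.
#' @export
flag_startles <- function(trace, cycles, startle_threshold = 45, window = 5L) {
  d <- difference_signal(trace, window = window)
  for (i in seq_len(nrow(cycles))) {
    if (cycles$excluded[i]) next
    span <- seq.int(cycles$start[i] + 1L, cycles$end[i])
    if (any(d[span] > startle_threshold)) {
      cycles$excluded[i] <- TRUE
      cycles$exclusion_reason[i] <- "startle"
    }
  }
  cycles
}

#' Per-cycle activity metrics
#'
#' For one cycle, over its valid frames (black/failed frames excluded):
#' \describe{
#'   \item{max_tail_angle}{maximum of the difference signal (degrees);
#'     amplitude of the evoked movement.}
#'   \item{normalized_integral}{mean difference per valid frame (degrees);
#'     duration-invariant activity level, comparable across partial cycles.}
#'   \item{pct_above_threshold}{percentage of valid frames with difference
#'     strictly above `threshold`.}
#'   \item{active}{`TRUE` when `max_tail_angle > threshold`.}
#' }
#'
#' Frames exactly at the threshold do not count as above it.
#'
#' @param trace A [tail_trace()].
#' @param cycle A single-row slice of the [segment_cycles()] table.
#' @param threshold Activity threshold in degrees, default 5.
#' @param window Rolling-median window, default 5.
#' @param diff Optional precomputed [difference_signal()] for the whole
#'   trace (avoids recomputation in loops).
#' @return A one-row data frame of the four metrics.
#' @export
cycle_metrics <- function(trace, cycle, threshold = 5, window = 5L,
                          diff = NULL) {
  stopifnot(inherits(trace, "vsr_trace"), nrow(cycle) == 1L)
  if (is.null(diff)) diff <- difference_signal(trace, window = window)
  span <- seq.int(cycle$start + 1L, cycle$end)       # 1-based frame indices
  ok <- trace$valid[span]
  if (!any(ok)) {
    stop("degenerate cycle: no valid frames in cycle ", cycle$cycle_index,
         call. = FALSE)
  }
  d <- diff[span][ok]
  mx <- max(d)
  data.frame(max_tail_angle = mx,
             normalized_integral = sum(d) / length(d),
             pct_above_threshold = 100 * sum(d > threshold) / length(d),
             active = mx > threshold)
}

#' Full per-cycle metric table for a trace
#'
#' Runs [segment_cycles()], [flag_startles()] and [cycle_metrics()] and
#' returns one row per cycle. Metrics are computed for retained cycles;
#' excluded cycles carry `NA` metrics.
#'
#' @inheritParams cycle_metrics
#' @inheritParams flag_startles
#' @param larva_id Identifier copied into every row (defaults to the trace's
#'   `meta$larva_id`, or `"larva"`).
#' @return Data frame with columns `larva_id`, `cycle_index`, `epoch`,
#'   `start`, `end`, `start_time_s`, `excluded`, `exclusion_reason`,
#'   `max_tail_angle_deg`, `normalized_integral_deg`, `pct_above_threshold`,
#'   `active`.
#' @export
cycle_metrics_table <- function(trace, threshold = 5, window = 5L,
                                startle_threshold = 45, larva_id = NULL) {
  cycles <- segment_cycles(trace)
  cycles <- flag_startles(trace, cycles, startle_threshold, window)
  d <- difference_signal(trace, window = window)
  if (is.null(larva_id)) {
    larva_id <- if (!is.null(trace$meta$larva_id)) trace$meta$larva_id else "larva"
  }
  m <- data.frame(max_tail_angle = rep(NA_real_, nrow(cycles)),
                  normalized_integral = NA_real_,
                  pct_above_threshold = NA_real_, active = NA)
  for (i in which(!cycles$excluded)) {
    m[i, ] <- cycle_metrics(trace, cycles[i, ], threshold, window, diff = d)
  }
  data.frame(larva_id = larva_id,
             cycles[, c("cycle_index", "epoch", "start", "end",
                        "start_time_s", "excluded", "exclusion_reason")],
             max_tail_angle_deg = m$max_tail_angle,
             normalized_integral_deg = m$normalized_integral,
             pct_above_threshold = m$pct_above_threshold,
             active = as.logical(m$active),
             row.names = NULL)
}
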
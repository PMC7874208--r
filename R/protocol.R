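#' Stimulus protocol for the rotating-platform VSR assay
#'
#' Describes the yaw stimulus and recording geometry: a platform rocking
#' sinusoidally between `-amplitude` and `+amplitude` degrees at `frequency`
#' Hz while an infrared camera records at `fps` frames per second. Once per
#' stimulus cycle the illumination is paused for `black_pause_ms` so that an
#' all-black marker frame delimits the cycle. A trial consists of one or more
#' stimulation epochs separated by unrecorded rest periods.
#'
#' @param frequency Stimulus frequency in Hz. Default 0.53.
#' @param amplitude Platform excursion in degrees (`amplitude = 75` means
#'   rotation from -75 to +75 degrees). Default 75.
#' @param fps Recording frame rate in frames per second. Default 30.
#' @param frames_per_recording Number of frames in the default single-epoch
#'   recording. Default 1280 (about 42 s at 30 fps).
#' @param black_pause_ms Illumination pause used to record one marker frame,
#'   in milliseconds. Default 16. Metadata only; the marker frame occupies a
#'   single frame slot regardless.
#' @param epochs Optional data frame with columns `stim_s` (stimulation
#'   duration, seconds) and `rest_s` (rest that follows the epoch, seconds).
#'   When `NULL`, a single epoch of `frames_per_recording / fps` seconds with
#'   no rest is used.
#' @return An object of class `vsr_protocol`.
#' @seealso [protocol_prolonged()], [protocol_interval()], [make_stimulus()]
#' @examples
#' p <- stimulus_protocol()
#' frames_per_cycle(p)   # 56 frames at 30 fps / 0.53 Hz
#' @export
stimulus_protocol <- function(frequency = 0.53, amplitude = 75, fps = 30,
                              frames_per_recording = 1280,
                              black_pause_ms = 16, epochs = NULL) {
  if (!is.numeric(frequency) || length(frequency) != 1L || !is.finite(frequency) ||
      frequency <= 0) {
    stop("invalid protocol: `frequency` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("invalid protocol: `fps` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("invalid protocol: `amplitude` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(black_pause_ms) || black_pause_ms < 0) {
    stop("invalid protocol: `black_pause_ms` must be >= 0", call. = FALSE)
  }
  fpc <- floor(fps / frequency)
  if (is.null(epochs)) {
    if (!is.numeric(frames_per_recording) || frames_per_recording < 2 * fpc) {
      stop("invalid protocol: `frames_per_recording` must be at least two cycles (",
           2 * fpc, " frames)", call. = FALSE)
    }
    epochs <- data.frame(stim_s = frames_per_recording / fps, rest_s = 0)
  } else {
    epochs <- as.data.frame(epochs)
    if (!all(c("stim_s", "rest_s") %in% names(epochs)) || nrow(epochs) < 1L) {
      stop("invalid protocol: `epochs` needs columns stim_s and rest_s", call. = FALSE)
    }
    if (any(!is.finite(epochs$stim_s)) || any(!is.finite(epochs$rest_s)) ||
        any(epochs$stim_s < 0) || any(epochs$rest_s < 0)) {
      stop("invalid protocol: epoch durations must be finite and >= 0", call. = FALSE)
    }
    if (any(round(epochs$stim_s * fps) < 2 * fpc)) {
      stop("invalid protocol: every epoch must contain at least two stimulus cycles",
           call. = FALSE)
    }
  }
  structure(
    list(frequency = frequency, amplitude = amplitude, fps = fps,
         frames_per_recording = frames_per_recording,
         black_pause_ms = black_pause_ms, epochs = epochs),
    class = "vsr_protocol"
  )
}

#' Frames per stimulus cycle
#'
#' One cycle spans `floor(fps / frequency)` frames: 56 frames at the default
#' 30 fps and 0.53 Hz.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Integer number of frames in one stimulus cycle.
#' @export
frames_per_cycle <- function(protocol) {
  stopifnot(inherits(protocol, "vsr_protocol"))
  as.integer(floor(protocol$fps / protocol$frequency))
}

#' Total wall-clock duration of a protocol
#'
#' Sum of all stimulation epochs plus the rests between them (a rest after
#' the final epoch, if any, is included as scheduled).
#'
#' @param protocol A [stimulus_protocol()].
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "vsr_protocol"))
  sum(protocol$epochs$stim_s) + sum(protocol$epochs$rest_s)
}

#' Prolonged-stimulation protocol
#'
#' A single uninterrupted stimulation epoch, by default 252 s (over four
#' minutes of continuous yaw), used to expose long pauses in reflex activity.
#'
#' @param total_s Total stimulation duration in seconds. Default 252.
#' @param ... Passed to [stimulus_protocol()] (frequency, fps, ...).
#' @return A `vsr_protocol`.
#' @export
protocol_prolonged <- function(total_s = 252, ...) {
  stimulus_protocol(epochs = data.frame(stim_s = total_s, rest_s = 0), ...)
}

#' Defined-interval recovery protocol
#'
#' Six stimulation epochs (42 s each by default) separated by rests that
#' shrink from 20 s to 0 s in 5-s steps, totalling 302 s. Used to estimate
#' the minimal rest interval that restores reflex activity.
#'
#' @param stim_s Duration of each stimulation epoch in seconds. Default 42.
#' @param rests Rest durations between consecutive epochs, seconds.
#'   Default `c(20, 15, 10, 5, 0)`.
#' @param ... Passed to [stimulus_protocol()].
#' @return A `vsr_protocol`.
#' @export
protocol_interval <- function(stim_s = 42, rests = c(20, 15, 10, 5, 0), ...) {
  epochs <- data.frame(stim_s = rep(stim_s, length(rests) + 1L),
                       rest_s = c(rests, 0))
  stimulus_protocol(epochs = epochs, ...)
}

#' @export
print.vsr_protocol <- function(x, ...) {
  cat(sprintf("VSR stimulus protocol: %.2f Hz, +/-%g deg, %g fps (%d frames/cycle)\n",
              x$frequency, x$amplitude, x$fps, frames_per_cycle(x)))
  cat(sprintf("  %d epoch(s), total %.1f s\n", nrow(x$epochs), protocol_duration(x)))
  invisible(x)
}

#' Platform angle series and marker-frame schedule
#'
#' Expands a protocol into its recorded frames: platform angle
#' `amplitude * sin(2 * pi * frequency * t)` (with the phase restarting at
#' each epoch), absolute frame times that skip over unrecorded rests, the
#' epoch index of every frame, and the schedule of black marker frames placed
#' every [frames_per_cycle()] frames from the start of each epoch.
#'
#' @param protocol A [stimulus_protocol()].
#' @return A list with elements
#'   \describe{
#'     \item{time_s}{absolute time of each frame (s), including rest gaps}
#'     \item{epoch_time_s}{time since the start of the frame's epoch (s)}
#'     \item{platform_angle_deg}{platform angle at each frame}
#'     \item{epoch}{1-based epoch index per frame}
#'     \item{black_frames}{0-based indices of marker frames}
#'     \item{cycles}{data frame of 0-based half-open frame spans
#'       (`start`, `end`), epoch and `start_time_s` for every
#'       marker-delimited block, including trailing partial blocks}
#'     \item{frames_per_cycle}{frames in one full cycle}
#'   }
#' @export
make_stimulus <- function(protocol) {
  stopifnot(inherits(protocol, "vsr_protocol"))
  fpc <- frames_per_cycle(protocol)
  fps <- protocol$fps
  ep <- protocol$epochs

  time_s <- numeric(0); epoch_time <- numeric(0); epoch_id <- integer(0)
  black <- integer(0)
  cyc_start <- integer(0); cyc_end <- integer(0); cyc_epoch <- integer(0)
  offset <- 0L        # global frame offset
  t0 <- 0             # absolute time at epoch start
  for (e in seq_len(nrow(ep))) {
    n_e <- as.integer(round(ep$stim_s[e] * fps))
    tt <- (seq_len(n_e) - 1L) / fps
    time_s <- c(time_s, t0 + tt)
    epoch_time <- c(epoch_time, tt)
    epoch_id <- c(epoch_id, rep.int(e, n_e))
    b <- seq.int(0L, n_e - 1L, by = fpc)
    black <- c(black, offset + b)
    starts <- b
    ends <- c(b[-1L], n_e)
    keep <- ends > starts
    cyc_start <- c(cyc_start, offset + starts[keep])
    cyc_end <- c(cyc_end, offset + ends[keep])
    cyc_epoch <- c(cyc_epoch, rep.int(e, sum(keep)))
    offset <- offset + n_e
    t0 <- t0 + ep$stim_s[e] + ep$rest_s[e]
  }
  platform <- protocol$amplitude * sin(2 * pi * protocol$frequency * epoch_time)
  cycles <- data.frame(start = cyc_start, end = cyc_end, epoch = cyc_epoch)
  cycles$start_time_s <- time_s[cycles$start + 1L]
  list(time_s = time_s, epoch_time_s = epoch_time,
       platform_angle_deg = platform, epoch = epoch_id,
       black_frames = black, cycles = cycles, frames_per_cycle = fpc)
}
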
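#' Per-frame tail-angle trace
#'
#' Container for one recording: the signed tail angle per frame (degrees,
#' positive toward one fixed lateral side), the frame rate, the 0-based
#' indices of all-black marker frames, and a per-frame validity flag (black
#' and tracking-failure frames are invalid and excluded from metrics).
#'
#' @param angles Numeric vector of per-frame tail angles in degrees.
#' @param fps Frames per second.
#' @param black_frames Sorted 0-based indices of marker frames.
#' @param valid Logical vector, one per frame; defaults to `TRUE` everywhere
#'   except black frames.
#' @param time_s Optional absolute frame times (s); defaults to
#'   `(0:(n-1)) / fps`. Multi-epoch traces carry times that jump over rests.
#' @param epoch Optional 1-based epoch index per frame (defaults to all 1).
#' @param meta Free-form provenance list (genotype label, seed, protocol...).
#' @return An object of class `vsr_trace`.
#' @export
tail_trace <- function(angles, fps, black_frames = integer(0), valid = NULL,
                       time_s = NULL, epoch = NULL, meta = list()) {
  n <- length(angles)
  if (n < 1L || !is.numeric(angles)) {
    stop("invalid trace: `angles` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("invalid trace: `fps` must be a single positive number", call. = FALSE)
  }
  black_frames <- as.integer(black_frames)
  if (is.unsorted(black_frames, strictly = TRUE)) {
    stop("invalid trace: `black_frames` must be strictly increasing", call. = FALSE)
  }
  if (length(black_frames) && (min(black_frames) < 0L || max(black_frames) >= n)) {
    stop("invalid trace: `black_frames` out of range [0, n)", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) {
    stop("invalid trace: `valid` must match `angles` in length", call. = FALSE)
  }
  valid[black_frames + 1L] <- FALSE
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fps
  if (is.null(epoch)) epoch <- rep.int(1L, n)
  stopifnot(length(time_s) == n, length(epoch) == n)
  structure(
    list(angles = as.numeric(angles), fps = fps, black_frames = black_frames,
         valid = as.logical(valid), time_s = as.numeric(time_s),
         epoch = as.integer(epoch), meta = meta),
    class = "vsr_trace"
  )
}

#' @export
print.vsr_trace <- function(x, ...) {
  cat(sprintf("VSR tail trace: %d frames at %g fps, %d black frames, %d epoch(s)\n",
              length(x$angles), x$fps, length(x$black_frames),
              length(unique(x$epoch))))
  if (!is.null(x$meta$genotype)) cat("  genotype:", x$meta$genotype, "\n")
  invisible(x)
}

#' @export
length.vsr_trace <- function(x) length(x$angles)

#' Read / write a tail-angle trace as CSV
#'
#' The on-disk format has one row per frame and the mandatory header
#' `frame_index,time_s,tail_angle_deg,is_black_frame` (0-based frame index,
#' absolute time in seconds, signed angle in degrees, 0/1 marker flag).
#' An optional `epoch` column carries the 1-based epoch index for
#' multi-epoch trials and is preserved on round trip.
#'
#' @param path File path.
#' @param fps Frames per second of the recording (not stored in the CSV).
#' @return `read_trace_csv()` returns a [tail_trace()]; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path, fps = 30) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("frame_index", "time_s", "tail_angle_deg", "is_black_frame")
  if (!all(need %in% names(df))) {
    stop("trace CSV ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$frame_index), , drop = FALSE]
  tail_trace(angles = df$tail_angle_deg, fps = fps,
             black_frames = df$frame_index[df$is_black_frame == 1],
             time_s = df$time_s,
             epoch = if ("epoch" %in% names(df)) df$epoch else NULL,
             meta = list(source = path))
}

#' @param trace A [tail_trace()].
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "vsr_trace"))
  n <- length(trace$angles)
  df <- data.frame(frame_index = seq_len(n) - 1L,
                   time_s = trace$time_s,
                   tail_angle_deg = trace$angles,
                   is_black_frame = as.integer((seq_len(n) - 1L) %in% trace$black_frames))
  if (length(unique(trace$epoch)) > 1L) df$epoch <- trace$epoch
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
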
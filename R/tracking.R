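# 8-connected binary dilation by one pixel (used by the geodesic wavefront).
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

# Geodesic (within-mask) distance from a start pixel, in 8-connected steps.
geodesic_dist <- function(mask, start_rc) {
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  frontier <- matrix(FALSE, nrow(mask), ncol(mask))
  frontier[start_rc[1L], start_rc[2L]] <- TRUE
  d[frontier] <- 0
  k <- 0
  while (any(frontier)) {
    k <- k + 1
    newf <- dilate8(frontier) & mask & is.na(d)
    d[newf] <- k
    frontier <- newf
  }
  d
}

#' Detect all-black marker frames
#'
#' Marker frames are recorded with the illumination paused, so their mean
#' intensity collapses. A frame is flagged when its mean intensity falls
#' below `intensity_fraction` times the median per-frame mean intensity of
#' the sequence.
#'
#' @param frames List of grayscale frame matrices in `[0, 1]`.
#' @param intensity_fraction Threshold fraction in `(0, 1)`, default 0.1.
#' @return Sorted unique 0-based frame indices.
#' @export
detect_black_frames <- function(frames, intensity_fraction = 0.1) {
  if (!length(frames)) stop("empty frame sequence", call. = FALSE)
  stopifnot(intensity_fraction > 0, intensity_fraction < 1)
  means <- vapply(frames, mean, numeric(1))
  sort(unique(which(means < intensity_fraction * stats::median(means)) - 1L))
}

#' Extract the 10-point tail midline from one frame
#'
#' Segments the bright body region (largest connected component above
#' `threshold`), locates the swim bladder as the widest part of the body
#' (maximum of the distance transform), walks the region geodesically
#' toward the thinner end to find the tail tip, reduces the region to a
#' midline polyline (centroids of geodesic-distance bins), and resamples it
#' by arc length to exactly 10 points from the bladder end to the tip.
#'
#' @param frame Grayscale matrix in `[0, 1]`.
#' @param threshold Segmentation intensity threshold, default 0.2.
#' @return An object of class `vsr_midline`: list with `points` (10 x 2
#'   matrix of `(x = col, y = row)` coordinates, bladder first, tip last),
#'   `bladder_center`, `tip` (= `points[10, ]`) and `body_axis` (unit
#'   trunk direction estimated from the first midline segment).
#'   Frames without a trackable body (e.g. black marker frames, or a region
#'   touching 3+ image borders) raise a tracking-failure error.
#' @export
extract_midline <- function(frame, threshold = 0.2) {
  mask <- frame > threshold
  if (!any(mask)) {
    stop("tracking failure: no bright region above threshold", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask)
  lab <- if (is.matrix(lab)) lab else EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  borders <- sum(any(mask[1L, ]), any(mask[nrow(mask), ]),
                 any(mask[, 1L]), any(mask[, ncol(mask)]))
  if (borders >= 3L) {
    stop("tracking failure: body region touches ", borders, " image borders",
         call. = FALSE)
  }
  # restrict the geodesic computations to the body's bounding box,
  # padded by one background pixel so the distance transform sees an edge
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  r_off <- rr[1L] - 2L; c_off <- cc[1L] - 2L
  crop <- mask[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  mask <- matrix(FALSE, nrow(crop) + 2L, ncol(crop) + 2L)
  mask[2:(nrow(crop) + 1L), 2:(ncol(crop) + 1L)] <- crop

  dm <- EBImage::distmap(mask)
  dm <- if (is.matrix(dm)) dm else EBImage::imageData(dm)
  wide <- which(dm >= 0.9 * max(dm), arr.ind = TRUE)
  bladder <- c(mean(wide[, 2L]) + c_off, mean(wide[, 1L]) + r_off)  # (x, y)
  bl_px <- wide[1L, ]                                     # a pixel inside the blob

  d_b <- geodesic_dist(mask, bl_px)
  tip_px <- which(d_b == max(d_b, na.rm = TRUE), arr.ind = FALSE)[1L]
  tip_rc <- c((tip_px - 1L) %% nrow(mask) + 1L, (tip_px - 1L) %/% nrow(mask) + 1L)
  d_t <- geodesic_dist(mask, tip_rc)

  db <- d_t[bl_px[1L], bl_px[2L]]
  if (!is.finite(db) || db < 4) {
    stop("tracking failure: body region too small to trace", call. = FALSE)
  }
  # midline polyline: centroid of each 2-px geodesic-distance bin from the
  # tip, excluding pixels inside the bladder blob (they spread around the
  # bladder and would fold the polyline back on itself)
  r_blob <- max(dm)
  idx <- which(!is.na(d_t) & d_t <= db - r_blob)
  rc <- arrayInd(idx, dim(mask))
  bins <- floor(d_t[idx] / 2)
  cx <- tapply(rc[, 2L] + c_off, bins, mean)
  cy <- tapply(rc[, 1L] + r_off, bins, mean)
  ord <- order(as.numeric(names(cx)), decreasing = TRUE)   # bladder -> tip
  poly <- cbind(x = as.numeric(cx[ord]), y = as.numeric(cy[ord]))
  tip_idx <- which(!is.na(d_t) & d_t <= 1.5)
  tip_rc2 <- arrayInd(tip_idx, dim(mask))
  tipc <- c(mean(tip_rc2[, 2L]) + c_off, mean(tip_rc2[, 1L]) + r_off)
  poly <- rbind(bladder, poly, tipc)

  # resample to 10 points equally spaced by arc length
  seg <- sqrt(diff(poly[, 1L])^2 + diff(poly[, 2L])^2)
  arc <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(arc) > 1e-9)
  poly <- poly[keep, , drop = FALSE]; arc <- arc[keep]
  tgt <- seq(0, arc[length(arc)], length.out = 10L)
  pts <- cbind(x = stats::approx(arc, poly[, 1L], tgt)$y,
               y = stats::approx(arc, poly[, 2L], tgt)$y)
  axis_vec <- pts[2L, ] - pts[1L, ]
  axis_vec <- axis_vec / sqrt(sum(axis_vec^2))
  structure(list(points = pts, bladder_center = pts[1L, ], tip = pts[10L, ],
                 body_axis = axis_vec),
            class = "vsr_midline")
}

#' Signed tail angle of a midline
#'
#' The signed angle, in degrees, between the body axis and the chord from
#' the swim-bladder center to the tail tip, in `(-180, 180]`. The sign is
#' fixed by the cross product of axis and chord, so one lateral side is
#' consistently positive across frames when the same reference axis is
#' used.
#'
#' @param midline A `vsr_midline` from [extract_midline()].
#' @param body_axis Reference axis as a unit `(x, y)` vector; defaults to
#'   the midline's own trunk estimate. Pass a fixed axis (e.g. from the
#'   first frame of a recording) for a stimulus-independent sign
#'   convention.
#' @return Angle in degrees.
#' @export
compute_tail_angle <- function(midline, body_axis = midline$body_axis) {
  stopifnot(inherits(midline, "vsr_midline"))
  chord <- midline$tip - midline$bladder_center
  if (sqrt(sum(chord^2)) < 1e-9) {
    stop("undefined angle: zero-length bladder-to-tip chord", call. = FALSE)
  }
  cross <- body_axis[1L] * chord[2L] - body_axis[2L] * chord[1L]
  dot <- body_axis[1L] * chord[1L] + body_axis[2L] * chord[2L]
  atan2(cross, dot) * 180 / pi
}

#' Track a frame sequence into a tail-angle trace
#'
#' Composition of the tracking stage: detects black marker frames, extracts
#' the midline and tail angle of every illuminated frame against a body
#' axis fixed once from the first trackable frame, carries tracking
#' failures as invalid frames with angles linearly interpolated from the
#' nearest valid neighbors, and fails hard when more than
#' `max_failure_frac` of the illuminated frames are untrackable.
#'
#' @param frames List of grayscale matrices, or a directory of numbered PNG
#'   frames (passed to [read_frames_png()]).
#' @param protocol Optional [stimulus_protocol()] supplying `fps`.
#' @param fps Frames per second when no protocol is given. Default 30.
#' @param intensity_fraction Black-frame detection threshold fraction.
#' @param threshold Segmentation intensity threshold.
#' @param max_failure_frac Maximal tolerated fraction of tracking failures
#'   among illuminated frames, default 0.2.
#' @return A [tail_trace()]; `meta$n_failed` counts interpolated frames.
#' @export
track_video <- function(frames, protocol = NULL, fps = 30,
                        intensity_fraction = 0.1, threshold = 0.2,
                        max_failure_frac = 0.2) {
  if (is.character(frames)) frames <- read_frames_png(frames)
  if (!length(frames)) stop("empty frame sequence", call. = FALSE)
  if (!is.null(protocol)) fps <- protocol$fps
  black <- detect_black_frames(frames, intensity_fraction)
  n <- length(frames)
  is_black <- (seq_len(n) - 1L) %in% black

  angles <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  axis0 <- NULL
  n_failed <- 0L
  for (i in seq_len(n)) {
    if (is_black[i]) next
    ml <- tryCatch(extract_midline(frames[[i]], threshold),
                   error = function(e) NULL)
    if (is.null(ml)) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(axis0)) axis0 <- ml$body_axis
    angles[i] <- compute_tail_angle(ml, body_axis = axis0)
    valid[i] <- TRUE
  }
  n_lit <- sum(!is_black)
  if (n_lit == 0L || n_failed / n_lit > max_failure_frac) {
    stop(sprintf("unusable recording: %d of %d illuminated frames untrackable",
                 n_failed, n_lit), call. = FALSE)
  }
  ok <- which(!is.na(angles))
  if (length(ok) < 2L) stop("unusable recording: fewer than 2 tracked frames",
                            call. = FALSE)
  angles <- stats::approx(ok, angles[ok], xout = seq_len(n), rule = 2)$y
  tail_trace(angles = angles, fps = fps, black_frames = black, valid = valid,
             meta = list(n_failed = n_failed, body_axis = axis0))
}
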
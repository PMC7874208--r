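#' Geometry of the rendered synthetic larva
#'
#' Describes how [render_frames()] draws a head-embedded larva: image size,
#' the fixed swim-bladder position, the tail arc length and its thickness
#' taper (the body is widest at the bladder end and thinnest at the tip,
#' which is what the midline tracker relies on to orient itself), and the
#' head blob radius.
#'
#' @param image_size `c(rows, cols)` of the grayscale frame. Default
#'   `c(180, 180)`.
#' @param bladder `c(row, col)` of the swim-bladder center. Default
#'   `c(90, 50)`.
#' @param tail_length_px Arc length of the tail in pixels. Default 75.
#' @param tail_radius `c(base, tip)` half-thickness taper in pixels.
#' @param head_radius Radius of the head/bladder blob. Default 6.5.
#' @return A list of class `vsr_geometry`.
#' @export
larva_geometry <- function(image_size = c(180L, 180L), bladder = c(90, 50),
                           tail_length_px = 75, tail_radius = c(4, 1.2),
                           head_radius = 6.5) {
  structure(list(image_size = as.integer(image_size), bladder = bladder,
                 tail_length_px = tail_length_px, tail_radius = tail_radius,
                 head_radius = head_radius),
            class = "vsr_geometry")
}

# Draw one frame at tail angle alpha (degrees). The tail is a circular arc
# starting at the bladder tangent to the body axis (+col direction) with
# curvature chosen so the bladder-to-tip chord makes the angle alpha with
# the axis; positive alpha bends toward increasing row index.
render_larva <- function(alpha_deg, geom) {
  nr <- geom$image_size[1L]; nc <- geom$image_size[2L]
  alpha <- alpha_deg * pi / 180
  L <- geom$tail_length_px
  kappa <- 2 * alpha / L
  s <- seq(0, L, length.out = 160L)
  if (abs(kappa) < 1e-9) {
    xs <- s; ys <- rep(0, length(s))
  } else {
    xs <- sin(kappa * s) / kappa
    ys <- (1 - cos(kappa * s)) / kappa
  }
  col0 <- geom$bladder[2L]; row0 <- geom$bladder[1L]
  px <- col0 + xs; py <- row0 + ys
  r <- geom$tail_radius[1L] +
    (geom$tail_radius[2L] - geom$tail_radius[1L]) * s / L
  # head blob: two discs just anterior of the bladder along the body axis
  px <- c(col0, col0 - 6, px); py <- c(row0, row0, py)
  r <- c(geom$head_radius, geom$head_radius * 0.9, r)

  pad <- max(r) + 1.5
  if (any(px - pad < 1) || any(px + pad > nc) ||
      any(py - pad < 1) || any(py + pad > nr)) {
    stop("rendering error: tail angle ", alpha_deg,
         " deg places the larva outside the image", call. = FALSE)
  }
  img <- matrix(0, nr, nc)
  r0 <- floor(min(py) - pad); r1 <- ceiling(max(py) + pad)
  c0 <- floor(min(px) - pad); c1 <- ceiling(max(px) + pad)
  rows <- r0:r1; cols <- c0:c1
  RR <- matrix(rows, length(rows), length(cols))
  CC <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  patch <- matrix(0, length(rows), length(cols))
  for (i in seq_along(px)) {
    d <- sqrt((RR - py[i])^2 + (CC - px[i])^2)
    patch <- pmax(patch, pmin(pmax(r[i] + 0.5 - d, 0), 1))  # 1-px soft edge
  }
  img[rows, cols] <- patch
  img
}

#' Render a trace as a grayscale frame sequence
#'
#' One frame per trace sample: a bright curved larva (head/swim-bladder
#' blob at a fixed position, tail drawn as a smooth arc whose
#' bladder-to-tip chord makes the trace's tail angle with the body axis) on
#' a dark background. Black marker frames are rendered as all-zero images.
#' The rendered sequence is the ground-truth fixture for the tracking
#' module: re-tracking it should recover the input angles.
#'
#' @param trace A [tail_trace()].
#' @param geometry A [larva_geometry()].
#' @return List of numeric matrices in `[0, 1]`, one per frame.
#' @export
render_frames <- function(trace, geometry = larva_geometry()) {
  stopifnot(inherits(trace, "vsr_trace"))
  nr <- geometry$image_size[1L]; nc <- geometry$image_size[2L]
  black <- trace$black_frames + 1L
  lapply(seq_along(trace$angles), function(i) {
    if (i %in% black) matrix(0, nr, nc)
    else render_larva(trace$angles[i], geometry)
  })
}

#' Read / write a frame sequence as numbered PNG files
#'
#' Frames are stored as zero-padded numbered grayscale PNGs so that
#' lexicographic order equals temporal order.
#'
#' @param frames List of numeric matrices in `[0, 1]`.
#' @param dir Directory (created if missing).
#' @return `write_frames_png()` returns the file paths invisibly;
#'   `read_frames_png()` returns a list of matrices.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%05d.png", i - 1L))
    png::writePNG(frames[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  if (!dir.exists(dir)) stop("frame directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir, call. = FALSE)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img
  })
}
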
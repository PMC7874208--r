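geom <- larva_geometry()

test_that("black-frame detection flags dark frames against the median", {
  bright <- matrix(0.5, 20, 20)
  dark <- matrix(0, 20, 20)
  expect_identical(detect_black_frames(list(bright, dark, bright, bright)), 1L)
  expect_identical(detect_black_frames(list(bright, bright)), integer(0))
  expect_error(detect_black_frames(list()), "empty")
})

test_that("a straight larva yields a collinear midline and zero angle", {
  fr <- vsrquant:::render_larva(0, geom)
  ml <- extract_midline(fr)
  expect_identical(nrow(ml$points), 10L)
  expect_lt(max(abs(ml$points[, "y"] - geom$bladder[1])), 1)
  expect_lt(abs(compute_tail_angle(ml, body_axis = c(1, 0))), 1)
  expect_equal(ml$tip, ml$points[10L, ])
  # consecutive points roughly equally spaced by arc length
  seg <- sqrt(diff(ml$points[, 1])^2 + diff(ml$points[, 2])^2)
  expect_lt(max(seg) / min(seg), 1.5)
})

test_that("black or empty frames are tracking failures", {
  expect_error(extract_midline(matrix(0, 50, 50)), "tracking failure")
})

test_that("rendered angles are recovered within 2 degrees", {
  for (a in c(-40, -20, -5, 15, 35, 60)) {
    ml <- extract_midline(vsrquant:::render_larva(a, geom))
    expect_lt(abs(compute_tail_angle(ml, body_axis = c(1, 0)) - a), 2)
  }
})

test_that("angle computation follows the chord geometry", {
  mk <- function(chord) {
    structure(list(points = rbind(matrix(0, 9, 2), chord),
                   bladder_center = c(0, 0), tip = chord,
                   body_axis = c(1, 0)), class = "vsr_midline")
  }
  expect_equal(compute_tail_angle(mk(c(5, 0))), 0)
  expect_equal(compute_tail_angle(mk(c(0, 3))), 90)
  expect_equal(compute_tail_angle(mk(c(0, -3))), -90)
  expect_equal(compute_tail_angle(mk(c(1, 1))), 45)
  expect_error(compute_tail_angle(mk(c(0, 0))), "zero-length")
})

test_that("the tail angle is mirror-antisymmetric and rotation-equivariant", {
  for (a in c(12, 33)) {
    fr <- vsrquant:::render_larva(a, geom)
    ang <- compute_tail_angle(extract_midline(fr), body_axis = c(1, 0))
    # mirror about the horizontal body axis: rows flipped, angle negated
    ang_m <- compute_tail_angle(extract_midline(fr[nrow(fr):1, ]),
                                body_axis = c(1, 0))
    expect_equal(ang_m, -ang, tolerance = 0.15)
    # exact 90-degree frame rotation with a co-rotated reference axis
    fr_r <- t(fr)[ncol(fr):1, ]                 # rotate 90 deg clockwise
    ang_r <- compute_tail_angle(extract_midline(fr_r), body_axis = c(0, -1))
    expect_equal(ang_r, ang, tolerance = 0.15)
  }
})

test_that("geometry placing the tail outside the image is a rendering error", {
  tight <- larva_geometry(image_size = c(90, 90), bladder = c(45, 20),
                          tail_length_px = 75)
  expect_error(vsrquant:::render_larva(80, tight), "outside the image")
})

test_that("track_video round-trips a rendered recording", {
  p <- stimulus_protocol(frequency = 0.5, fps = 20, frames_per_recording = 120)
  tr <- simulate_trace(phenotype_wildtype(startle_rate = 0), p, seed = 3)
  frames <- render_frames(tr)
  tr2 <- track_video(frames, protocol = p)
  expect_identical(tr2$black_frames, tr$black_frames)
  expect_identical(tr2$fps, p$fps)
  ok <- tr$valid & tr2$valid
  rms <- sqrt(mean((tr2$angles[ok] - tr$angles[ok])^2))
  expect_lt(rms, 2)
  # static bright frames: constant angle, no black frames
  static <- replicate(12, vsrquant:::render_larva(10, geom), simplify = FALSE)
  trs <- track_video(static, fps = 30)
  expect_identical(trs$black_frames, integer(0))
  expect_lt(diff(range(trs$angles)), 1e-9)
})

test_that("mostly untrackable recordings fail hard", {
  good <- vsrquant:::render_larva(5, geom)
  noise <- matrix(0.5, 180, 180)    # bright but structureless: touches no borders?
  noise[1, ] <- 0.5                 # fills the frame -> touches all 4 borders
  bad <- matrix(1, 180, 180)
  frames <- c(list(good, good), replicate(8, bad, simplify = FALSE))
  expect_error(track_video(frames, fps = 30), "unusable")
})
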
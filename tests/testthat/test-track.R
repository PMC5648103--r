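make_roi <- function(tpl = single_tube_template()) {
  build_rois(tpl, identity_placement(tpl))[[1]]
}

test_that("background init is the per-pixel median and patches a parked fly", {
  tpl <- single_tube_template()
  roi <- make_roi(tpl)
  # empty static scene: model equals the scene exactly
  empty <- render_frame(tpl, noise_sd = 0)
  fs <- frame_seq(rep(list(empty), 5), 0:4)
  m <- init_background(fs, roi, n_init = 5)
  expect_equal(m$model, ethotrack:::crop_frame(empty, roi$bbox) + 0,
               tolerance = 1e-12)
  expect_error(init_background(fs, roi, n_init = 0), "n_init")
  expect_error(init_background(frame_seq(list(), numeric(0)), roi), "empty")

  # fly present in < half the init frames at any given pixel: median
  # excludes it (oracle: per-pixel median computed directly)
  frames <- lapply(c(10, 25, 40, 55, 50), function(x)
    render_frame(tpl, data.frame(roi = 1, x_mm = x, y_mm = 0), noise_sd = 0))
  fs2 <- frame_seq(frames, 0:4)
  m2 <- init_background(fs2, roi, n_init = 5, bootstrap_fly = FALSE)
  crops <- lapply(frames, function(f) ethotrack:::crop_frame(f, roi$bbox))
  arr <- array(unlist(crops), c(nrow(crops[[1]]), ncol(crops[[1]]), 5))
  expect_equal(m2$model, apply(arr, 1:2, median), tolerance = 1e-12)
  # no pixel retains the fly: model matches the empty scene
  expect_lt(max(abs(m2$model - ethotrack:::crop_frame(empty, roi$bbox))), 1e-9)

  # fly parked through all init frames: bootstrap patch removes it
  parked <- render_frame(tpl, data.frame(roi = 1, x_mm = 30, y_mm = 0),
                         noise_sd = 0)
  fs3 <- frame_seq(rep(list(parked), 5), 0:4)
  m3 <- init_background(fs3, roi, n_init = 5, bootstrap_fly = TRUE)
  expect_lt(max(abs(m3$model - ethotrack:::crop_frame(empty, roi$bbox))), 25)
  blobs <- segment_foreground(m3, parked, roi, threshold = 50)
  expect_equal(nrow(blobs), 1)
})

test_that("background update is exponential and selective", {
  tpl <- single_tube_template()
  roi <- make_roi(tpl)
  empty <- render_frame(tpl, noise_sd = 0)
  fs <- frame_seq(list(empty), 0)
  m <- init_background(fs, roi, n_init = 1, alpha = 0)
  other <- render_frame(tpl, noise_sd = 2, seed = 1)
  m0 <- update_background(m, other, roi)
  expect_equal(m0$model, m$model)           # alpha = 0: unchanged
  m$alpha <- 1
  m1 <- update_background(m, other, roi)
  expect_equal(m1$model, ethotrack:::crop_frame(other, roi$bbox) + 0)
  expect_error(update_background(m, other[1:10, 1:10], roi), "shape")
})

test_that("selective update keeps a long-parked fly segmentable", {
  tpl <- single_tube_template()
  roi <- make_roi(tpl)
  alpha <- 0.05
  n <- ceiling(10 / alpha)   # 200 frames parked at one spot
  parked <- render_frame(tpl, data.frame(roi = 1, x_mm = 42, y_mm = 0),
                         noise_sd = 0)
  fs <- frame_seq(rep(list(parked), n), seq_len(n) - 1)
  tr <- track_roi(fs, roi, track_params(alpha = alpha, threshold = 50))
  expect_false(any(tr$is_inferred[-(1:5)]))
  expect_lt(max(abs(tr$x_mm - 42)), 0.5)
})

test_that("segmentation reports blob moments and respects min_area", {
  tpl <- single_tube_template()
  roi <- make_roi(tpl)
  empty <- render_frame(tpl, noise_sd = 0)
  m <- init_background(frame_seq(list(empty), 0), roi, n_init = 1)
  # frame identical to model: empty blob set
  expect_equal(nrow(segment_foreground(m, empty, roi, threshold = 25)), 0)
  # one rendered ellipse: one blob, centroid within 0.5 px of truth
  fr <- render_frame(tpl, data.frame(roi = 1, x_mm = 20, y_mm = -0.8),
                     noise_sd = 0)
  b <- segment_foreground(m, fr, roi, threshold = 25)
  expect_equal(nrow(b), 1)
  truth <- apply_transform(identity_placement(tpl),
                           cbind(20, -0.8 + tpl$tube_width_mm / 2))
  expect_lt(abs(b$x - truth[1]), 0.5)
  expect_lt(abs(b$y - truth[2]), 0.5)
  # two ellipses: both reported
  fr2 <- ethotrack:::draw_ellipse_px(fr + 0,
                                     truth[1] + 150, truth[2], 12.5, 5, 0, 40)
  fr2 <- matrix(as.integer(round(fr2)), nrow(fr2))
  b2 <- segment_foreground(m, fr2, roi, threshold = 25)
  expect_equal(nrow(b2), 2)
})

test_that("track points carry moment ellipses, carry-forward and selection rules", {
  tpl <- single_tube_template()
  roi <- make_roi(tpl)
  empty <- render_frame(tpl, noise_sd = 0)
  m <- init_background(frame_seq(list(empty), 0), roi, n_init = 1)
  # a 10 x 4 px ellipse at 30 degrees, via the renderer
  ctr <- apply_transform(identity_placement(tpl), cbind(30, 2.5))
  fr <- ethotrack:::draw_ellipse_px(empty + 0, ctr[1], ctr[2], 5, 2, 30, 40)
  fr <- matrix(as.integer(round(fr)), nrow(fr))
  b <- segment_foreground(m, fr, roi, min_area_px = 10, threshold = 25)
  tp <- extract_track_point(b, NULL, 1, roi)
  expect_lt(abs(tp$w - 10) / 10, 0.1)
  expect_lt(abs(tp$h - 4) / 4, 0.1)
  expect_lt(min(abs(tp$phi - 30), abs(tp$phi - 210) %% 180), 3)
  expect_false(tp$is_inferred)

  # empty blob set: carry forward flagged as inferred
  eb <- segment_foreground(m, empty, roi, threshold = 25)
  tp2 <- extract_track_point(eb, tp, 2, roi)
  expect_true(tp2$is_inferred)
  expect_equal(tp2$x, tp$x)
  expect_error(extract_track_point(eb, NULL, 1, roi),
               class = "no_animal_found")
  expect_error(extract_track_point(eb, tp, tp$t, roi), "exceed")

  # nearest-to-previous selection (brute-force oracle)
  blobs <- data.frame(area = c(100, 90), x = c(100, 300), y = c(50, 52),
                      mxx = 4, mxy = 0, myy = 2, weight = 100)
  class(blobs) <- c("blob_set", "data.frame")
  prev <- data.frame(t = 0, x = 280, y = 50, x_mm = 0, y_mm = 0,
                     w = 10, h = 4, phi = 0, is_inferred = FALSE)
  d <- (blobs$x - prev$x)^2 + (blobs$y - prev$y)^2
  sel <- extract_track_point(blobs, prev, 1, roi)
  expect_equal(sel$x, blobs$x[which.min(d)])
})

test_that("tracking a synthetic video recovers the ground truth", {
  gen <- quick_recording(duration_s = 90, fps = 3, seed = 31)
  reg <- register_arena(gen$frames$frames[[1]], gen$template)
  tr <- track_roi(gen$frames, reg$rois[[1]])
  expect_equal(tr$t, gen$frames$t)   # timestamps preserved exactly
  d <- position_discrepancy(tr, gen$truth$positions[, c("t", "x_mm", "y_mm")])
  expect_lt(d$median_um, 100)        # well under one pixel (100 um)
  expect_equal(d$fraction_exceeding_body_length, 0)
})

test_that("an immobile fly tracks with sub-threshold velocity", {
  pr <- behavior_program("immobile", 90)
  gen <- quick_recording(duration_s = 90, fps = 3, seed = 33, program = pr)
  reg <- register_arena(gen$frames$frames[[1]], gen$template)
  tr <- track_roi(gen$frames, reg$rois[[1]])
  expect_lt(stats::sd(tr$x_mm), 1)
  fw <- classify_windows(windowed_features(tr))
  expect_true(all(fw$label[!fw$missing] == "immobile"))
})
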
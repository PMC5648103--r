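# Adaptive background-subtraction tracker, one fly per ROI.
#
# Pipeline (a reconstruction of the platform's default real-time tracker,
# whose exact internals are not publicly specified): per-pixel median
# initialization of the background, selective exponential update (pixels
# under the detected blob are excluded so a parked fly is never absorbed),
# positive-difference segmentation (the imaging polarity is fixed: fly
# darker than background) with an Otsu threshold estimated from the first
# difference images, and ellipse parameters from intensity-weighted second
# moments.

crop_frame <- function(frame, bbox) {
  frame[(bbox[2]:bbox[4]) + 1, (bbox[1]:bbox[3]) + 1, drop = FALSE]
}

# Logical mask of tube pixels (with pads) inside the ROI's crop bbox.
roi_crop_mask <- function(roi) {
  b <- roi$bbox
  xs <- b[1]:b[3]; ys <- b[2]:b[4]
  s <- 1 / roi$mm_per_px
  ctr <- roi$food_center + roi$axis * (roi$tube_length_mm / 2) * s
  DX <- matrix(xs - ctr[1], length(ys), length(xs), byrow = TRUE)
  DY <- matrix(ys - ctr[2], length(ys), length(xs))
  U <- roi$axis[1] * DX + roi$axis[2] * DY
  V <- roi$perp[1] * DX + roi$perp[2] * DY
  abs(U) <= roi$tube_length_mm / 2 * s + roi$pad_ax &
    abs(V) <= roi$tube_width_mm / 2 * s + roi$pad_tr
}

#' Tracker parameters
#'
#' @param alpha Background learning rate in [0, 1] (default 0.05).
#' @param n_init Number of initial frames for the median background.
#' @param min_area_px Minimum blob area in pixels.
#' @param threshold Difference threshold; `NULL` = estimate by Otsu from the
#'   first `n_threshold` difference images (floored at `threshold_floor`).
#' @param n_threshold Frames pooled for threshold estimation.
#' @param threshold_floor Lower bound on the difference threshold.
#' @param n_grace Frames allowed before the first detection must occur.
#' @param bootstrap_fly Patch the initial background under a fly that was
#'   parked throughout the init frames (see [init_background()]).
#' @return List of class `track_params`.
#' @export
track_params <- function(alpha = 0.05, n_init = 5, min_area_px = 40,
                         threshold = NULL, n_threshold = 50,
                         threshold_floor = 12, n_grace = 25,
                         bootstrap_fly = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1, n_init >= 1)
  structure(list(alpha = alpha, n_init = n_init, min_area_px = min_area_px,
                 threshold = threshold, n_threshold = n_threshold,
                 threshold_floor = threshold_floor, n_grace = n_grace,
                 bootstrap_fly = bootstrap_fly), class = "track_params")
}

#' Initialize the per-ROI background model
#'
#' The model is the per-pixel median of the first `n_init` ROI crops: a
#' pixel occupied by the fly in fewer than half of the init frames takes its
#' background value. A fly that dwells at one spot through half or more of
#' the init window leaks into the median; because the tubes are backlit,
#' no fly-sized dark blob can be genuine background, so when
#' `bootstrap_fly` is set any such blob found in the model itself is
#' patched out with the local background estimate. An immobile fly is then
#' segmentable from the first frame.
#'
#' @param frames A [frame_seq()].
#' @param roi A `roi`.
#' @param n_init Number of init frames (>= 1).
#' @param alpha Learning rate stored on the model for later updates.
#' @param min_area_px Minimum blob area for the bootstrap patch.
#' @param bootstrap_fly Enable the parked-fly patch.
#' @return Object of class `background_model`: `model` (double matrix, crop
#'   shape), `alpha`, `frame_count`, `mask` (tube pixels), `bbox`.
#' @export
init_background <- function(frames, roi, n_init = 5, alpha = 0.05,
                            min_area_px = 40, bootstrap_fly = TRUE) {
  if (!length(frames$frames)) stop("empty frame sequence")
  if (n_init < 1) stop("n_init must be >= 1")
  n_init <- min(n_init, length(frames$frames))
  crops <- lapply(frames$frames[seq_len(n_init)],
                  function(f) crop_frame(f, roi$bbox))
  M <- if (n_init == 1) crops[[1]] + 0 else {
    arr <- array(unlist(crops), dim = c(nrow(crops[[1]]), ncol(crops[[1]]),
                                        n_init))
    apply(arr, c(1, 2), stats::median)
  }
  mask <- roi_crop_mask(roi)
  if (bootstrap_fly && min(M[mask]) < stats::median(M[mask]) - 60) {
    # only when the model holds fly-level contrast (a backlit background
    # varies far less than the ~160-unit fly/background gap)
    bg_est <- stats::median(M[mask])
    dark <- (M < (bg_est + min(M[mask])) / 2) & mask
    if (any(dark)) {
      lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(dark * 1))),
                    nrow(dark))
      areas <- tabulate(lab[lab > 0])
      for (l in which(areas >= min_area_px)) {
        grown <- EBImage::dilate(EBImage::Image((lab == l) * 1),
                                 EBImage::makeBrush(7, "disc"))
        M[matrix(as.numeric(grown), nrow(dark)) > 0] <- bg_est
      }
    }
  }
  structure(list(model = M, alpha = alpha, frame_count = n_init,

                 mask = mask, bbox = roi$bbox),
            class = "background_model")
}

#' Update the background model
#'
#' Exponential update `model <- (1 - alpha) * model + alpha * frame`,
#' applied only to pixels outside `exclude` (the current detected blob,
#' dilated): the selective update is what keeps a long-parked fly from
#' being absorbed into the background.
#'
#' @param model A `background_model`.
#' @param frame Full frame matrix (cropped internally).
#' @param roi The `roi` the model belongs to.
#' @param exclude Optional logical matrix (crop shape) of pixels to skip.
#' @return The updated `background_model`.
#' @export
update_background <- function(model, frame, roi, exclude = NULL) {
  if (nrow(frame) <= roi$bbox[4] || ncol(frame) <= roi$bbox[3])
    stop("frame/model shape mismatch")
  cr <- crop_frame(frame, roi$bbox)
  if (!all(dim(cr) == dim(model$model)))
    stop("frame/model shape mismatch")
  upd <- (1 - model$alpha) * model$model + model$alpha * cr
  if (!is.null(exclude)) upd[exclude] <- model$model[exclude]
  model$model <- upd
  model$frame_count <- model$frame_count + 1L
  model
}

#' Segment foreground blobs in one ROI
#'
#' Thresholds the positive difference `model - frame` (the fly is darker
#' than the background) restricted to the tube mask, labels connected
#' components, and reports every blob with area >= `min_area_px` with its
#' intensity-weighted centroid and second central moments.
#'
#' @param model A `background_model`.
#' @param frame Full frame matrix.
#' @param roi The `roi`.
#' @param min_area_px Minimum blob area (px).
#' @param threshold Difference threshold (intensity units).
#' @return Data frame (class `blob_set`) with `area`, `x`, `y` (frame px,
#'   0-based), `mxx`, `mxy`, `myy`, `weight`; attribute `mask` holds the
#'   binary foreground (crop shape). Empty when nothing is segmented.
#' @export
segment_foreground <- function(model, frame, roi, min_area_px = 40,
                               threshold = 25) {
  cr <- crop_frame(frame, roi$bbox)
  diffm <- model$model - cr
  bin <- (diffm > threshold) & model$mask
  empty <- data.frame(area = integer(0), x = numeric(0), y = numeric(0),
                      mxx = numeric(0), mxy = numeric(0), myy = numeric(0),
                      weight = numeric(0))
  if (!any(bin)) {
    attr(empty, "mask") <- bin
    class(empty) <- c("blob_set", "data.frame")
    return(empty)
  }
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bin * 1))),
                nrow(bin))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) {
    attr(empty, "mask") <- bin & FALSE
    class(empty) <- c("blob_set", "data.frame")
    return(empty)
  }
  rows <- lapply(keep, function(l) {
    idx <- which(lab == l)
    yy <- (idx - 1) %% nrow(bin) + roi$bbox[2]
    xx <- (idx - 1) %/% nrow(bin) + roi$bbox[1]
    w <- diffm[idx]
    sw <- sum(w)
    cx <- sum(w * xx) / sw; cy <- sum(w * yy) / sw
    data.frame(area = areas[l], x = cx, y = cy,
               mxx = sum(w * (xx - cx)^2) / sw,
               mxy = sum(w * (xx - cx) * (yy - cy)) / sw,
               myy = sum(w * (yy - cy)^2) / sw,
               weight = sw)
  })
  out <- do.call(rbind, rows)
  fg <- bin
  fg[lab == 0 | !(lab %in% keep)] <- FALSE
  attr(out, "mask") <- fg
  class(out) <- c("blob_set", "data.frame")
  out
}

#' Build one track point from segmented blobs
#'
#' With at least one blob, selects the blob nearest the previous point
#' (largest blob when there is no previous point) and derives the ellipse
#' parameters from its second moments: full axes `w >= h` and orientation
#' `phi` in degrees modulo 180 (head/tail ambiguity is not resolved by
#' moments). With no blob, the previous position is carried forward and
#' flagged `is_inferred`.
#'
#' @param blobs A `blob_set`.
#' @param prev Previous track point (one-row data frame) or `NULL`.
#' @param t Timestamp (seconds); must exceed `prev$t`.
#' @param roi The `roi` (for the mm conversion).
#' @return One-row data frame with `t`, `x`, `y` (frame px), `x_mm`,
#'   `y_mm`, `w`, `h`, `phi`, `is_inferred`.
#' @export
extract_track_point <- function(blobs, prev, t, roi) {
  if (!is.null(prev) && t <= prev$t) stop("t must exceed prev$t")
  if (!nrow(blobs)) {
    if (is.null(prev))
      et_stop("no_animal_found", "no blob found and no previous position")
    out <- prev
    out$t <- t
    out$is_inferred <- TRUE
    return(out)
  }
  sel <- if (is.null(prev)) which.max(blobs$area)
         else which.min((blobs$x - prev$x)^2 + (blobs$y - prev$y)^2)
  b <- blobs[sel, ]
  C <- matrix(c(b$mxx, b$mxy, b$mxy, b$myy), 2)
  e <- eigen(C, symmetric = TRUE)
  wpx <- 4 * sqrt(max(e$values[1], 1e-12))
  hpx <- 4 * sqrt(max(e$values[2], 1e-12))
  v <- e$vectors[, 1]
  phi <- rad2deg(atan2(v[2], v[1])) %% 180
  mm <- roi_local_mm(roi, c(b$x, b$y))
  data.frame(t = t, x = b$x, y = b$y, x_mm = mm[1], y_mm = mm[2],
             w = wpx, h = hpx, phi = phi, is_inferred = FALSE)
}

#' Track one ROI across a frame sequence
#'
#' Runs the full adaptive background-subtraction pipeline on one ROI and
#' returns one track point per frame, preserving the (possibly non-uniform)
#' input timestamps. Frames before the first detection are back-filled from
#' the first real point and flagged `is_inferred`; if no blob is found in
#' the first `n_grace` frames, `no_animal_found` is raised.
#'
#' @param frames A [frame_seq()].
#' @param roi A `roi`.
#' @param params A [track_params()].
#' @return Data frame of class `trajectory` (one row per frame) with
#'   attributes `roi_index` and `mm_per_px`.
#' @export
track_roi <- function(frames, roi, params = track_params()) {
  n <- length(frames$frames)
  if (!n) stop("empty frame sequence")
  model <- init_background(frames, roi, n_init = params$n_init,
                           alpha = params$alpha,
                           min_area_px = params$min_area_px,
                           bootstrap_fly = params$bootstrap_fly)
  thr <- params$threshold
  if (is.null(thr)) {
    k <- min(params$n_threshold, n)
    pool <- unlist(lapply(frames$frames[seq_len(k)], function(f) {
      d <- model$model - crop_frame(f, roi$bbox)
      d[model$mask & d > 0]
    }))
    thr <- max(otsu255(pool), params$threshold_floor)
  }
  brush <- EBImage::makeBrush(7, "disc")
  pts <- vector("list", n)
  prev <- NULL
  first_real <- NA_integer_
  for (i in seq_len(n)) {
    blobs <- segment_foreground(model, frames$frames[[i]], roi,
                                min_area_px = params$min_area_px,
                                threshold = thr)
    tp <- tryCatch(
      extract_track_point(blobs, prev, frames$t[i], roi),
      ethotrack_error = function(e) {
        if (i > params$n_grace)
          et_stop("no_animal_found",
                  "no blob found in the first %d frames of ROI %d",
                  params$n_grace, roi$index)
        NULL
      })
    if (!is.null(tp)) {
      if (is.na(first_real)) first_real <- i
      pts[[i]] <- tp
      prev <- tp
    }
    exclude <- NULL
    if (nrow(blobs)) {
      fg <- attr(blobs, "mask")
      exclude <- matrix(as.numeric(EBImage::dilate(EBImage::Image(fg * 1),
                                                   brush)),
                        nrow(fg)) > 0
    }
    model <- update_background(model, frames$frames[[i]], roi, exclude)
  }
  if (is.na(first_real))
    et_stop("no_animal_found", "no blob ever found in ROI %d", roi$index)
  # back-fill frames before the first detection
  if (first_real > 1) {
    for (i in seq_len(first_real - 1)) {
      tp <- pts[[first_real]]
      tp$t <- frames$t[i]
      tp$is_inferred <- TRUE
      pts[[i]] <- tp
    }
  }
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  attr(out, "roi_index") <- roi$index
  attr(out, "mm_per_px") <- roi$mm_per_px
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Register and track a whole arena
#'
#' Registers the template on the first frame, then tracks every ROI.
#'
#' @param frames A [frame_seq()].
#' @param template An `arena_template`.
#' @param params A [track_params()].
#' @param roi_indices Optional subset of ROI indices to track.
#' @return List with `registration` and `trajectories` (named by ROI index).
#' @export
track_arena <- function(frames, template, params = track_params(),
                        roi_indices = NULL) {
  reg <- register_arena(frames$frames[[1]], template)
  rois <- reg$rois
  if (!is.null(roi_indices))
    rois <- Filter(function(r) r$index %in% roi_indices, rois)
  trajs <- lapply(rois, function(r) track_roi(frames, r, params))
  names(trajs) <- vapply(rois, function(r) as.character(r$index), character(1))
  list(registration = reg, trajectories = trajs)
}
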
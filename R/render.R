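# Synthetic imaging model: infrared-backlit tubes seen from above.
# Light arena background (200/255), slightly lighter tube interior (215),
# dark fiducial discs and dark fly ellipses (40), additive Gaussian pixel
# noise clipped to [0, 255]. Shapes are drawn with an analytic anti-aliased
# edge so intensity-weighted centroids are exact to well below a pixel.

BG_ARENA <- 200
BG_TUBE <- 215
INK_DARK <- 40
FLY_SEMI_AXES_MM <- c(1.25, 0.5)  # 2.5 mm x 1 mm body

# Blend an anti-aliased filled ellipse into canvas (0-based px coords).
draw_ellipse_px <- function(canvas, cx, cy, a, b, phi_deg, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- max(a, b) + 2
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  DX <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  DY <- matrix(ys - cy, length(ys), length(xs))
  th <- deg2rad(phi_deg)
  U <- cos(th) * DX + sin(th) * DY
  V <- -sin(th) * DX + cos(th) * DY
  M <- sqrt((U / a)^2 + (V / b)^2)
  G <- sqrt(U^2 / a^4 + V^2 / b^4) / pmax(M, 1e-9)
  D <- (M - 1) / pmax(G, 1e-9)          # approx signed distance in px
  cov <- clamp(0.5 - D, 0, 1)
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  canvas[ys + 1, xs + 1] <- sub * (1 - cov) + value * cov
  canvas
}

draw_disc_px <- function(canvas, cx, cy, r, value) {
  draw_ellipse_px(canvas, cx, cy, r, r, 0, value)
}

# Integer pool encoding the distribution of round(N(0, sd)): sampling from
# the pool is distributionally equivalent to adding Gaussian noise and
# rounding, but runs in integer arithmetic.
make_noise_pool <- function(sd, size = 65536L) {
  if (sd <= 0) return(NULL)
  k <- seq(-ceiling(6 * sd), ceiling(6 * sd))
  p <- stats::pnorm((k + 0.5) / sd) - stats::pnorm((k - 0.5) / sd)
  counts <- round(p / sum(p) * size)
  counts[k == 0] <- counts[k == 0] + (size - sum(counts))
  rep(as.integer(k), counts)
}

# Static scene for a template under a placement: tubes + fiducials, no flies.
render_static <- function(template, transform = identity_placement(template)) {
  w <- template$frame_px[1]; h <- template$frame_px[2]
  canvas <- matrix(BG_ARENA, h, w)
  s <- transform_scale(transform)
  # tube interiors (hard-edged rectangles via local coordinates)
  for (r in template$rois_mm) {
    crn <- apply_transform(transform, r$corners)
    ctr <- colMeans(crn)
    ax <- crn[4, ] - crn[1, ]; Lpx <- sqrt(sum(ax^2)); ax <- ax / Lpx
    pp <- c(-ax[2], ax[1])
    Wpx <- abs(sum((crn[2, ] - crn[1, ]) * pp))
    x0 <- max(0, floor(min(crn[, 1]))); x1 <- min(w - 1, ceiling(max(crn[, 1])))
    y0 <- max(0, floor(min(crn[, 2]))); y1 <- min(h - 1, ceiling(max(crn[, 2])))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    DX <- matrix(xs - ctr[1], length(ys), length(xs), byrow = TRUE)
    DY <- matrix(ys - ctr[2], length(ys), length(xs))
    U <- ax[1] * DX + ax[2] * DY
    V <- pp[1] * DX + pp[2] * DY
    inside <- abs(U) <= Lpx / 2 & abs(V) <= Wpx / 2
    sub <- canvas[ys + 1, xs + 1, drop = FALSE]
    sub[inside] <- BG_TUBE
    canvas[ys + 1, xs + 1] <- sub
  }
  fpx <- apply_transform(transform, template$fiducials_mm)
  for (i in 1:3)
    canvas <- draw_disc_px(canvas, fpx[i, 1], fpx[i, 2],
                           template$fiducial_radius_mm * s, INK_DARK)
  canvas
}

# ROI-local (x_mm from food end, y_mm transverse) -> template mm point.
roi_local_to_template_mm <- function(roi_tmpl, x_mm, y_mm, tube_length_mm) {
  crn <- roi_tmpl$corners
  ycen <- mean(crn[, 2])
  if (identical(roi_tmpl$food_end, "right"))
    cbind(max(crn[, 1]) - x_mm, ycen + y_mm)
  else
    cbind(min(crn[, 1]) + x_mm, ycen + y_mm)
}

#' Render one synthetic arena frame
#'
#' Draws the arena (tube interiors and the three fiducial discs) under a
#' placement, plus one dark anti-aliased fly ellipse (2.5 mm x 1 mm at
#' calibration) per entry of `fly_states`, then adds clipped Gaussian pixel
#' noise.
#'
#' @param template An `arena_template`.
#' @param fly_states Data frame with columns `roi`, `x_mm` (mm from the food
#'   end), `y_mm` (mm transverse from the tube axis) and optionally
#'   `phi_deg` (body angle relative to the tube axis). May be empty.
#' @param noise_sd Gaussian pixel-noise SD (intensity units).
#' @param seed Integer seed for the noise, or `NULL`.
#' @param transform Placement (`affine2d`); identity placement by default.
#' @param static Optional precomputed static scene from the same placement
#'   (an internal speed-up used by [generate_arena_frames()]).
#' @return Integer matrix (rows = y, cols = x) with values in 0..255.
#' @export
render_frame <- function(template, fly_states = NULL, noise_sd = 5,
                         seed = NULL, transform = identity_placement(template),
                         static = NULL) {
  canvas <- static %||% render_static(template, transform)
  s <- transform_scale(transform)
  if (!is.null(fly_states) && nrow(fly_states)) {
    roi_idx <- vapply(template$rois_mm, function(r) as.integer(r$index),
                      integer(1))
    for (i in seq_len(nrow(fly_states))) {
      fs <- fly_states[i, ]
      j <- match(as.integer(fs$roi), roi_idx)
      if (is.na(j)) stop("unknown ROI index: ", fs$roi)
      rt <- template$rois_mm[[j]]
      W <- template$tube_width_mm
      if (fs$x_mm < 0 || fs$x_mm > template$tube_length_mm ||
          abs(fs$y_mm) > W / 2)
        et_stop("position_outside_roi",
                "fly position (%.2f, %.2f) outside ROI %d",
                fs$x_mm, fs$y_mm, fs$roi)
      p_mm <- roi_local_to_template_mm(rt, fs$x_mm, fs$y_mm,
                                       template$tube_length_mm)
      p_px <- apply_transform(transform, p_mm)
      crn <- apply_transform(transform, rt$corners)
      ax <- crn[4, ] - crn[1, ]
      axis_deg <- rad2deg(atan2(ax[2], ax[1]))
      phi <- axis_deg + (fs$phi_deg %||% 0)
      if (is.na(phi)) phi <- axis_deg
      canvas <- draw_ellipse_px(canvas, p_px[1], p_px[2],
                                FLY_SEMI_AXES_MM[1] * s,
                                FLY_SEMI_AXES_MM[2] * s, phi, INK_DARK)
    }
  }
  with_seed(seed, {
    if (noise_sd > 0)
      canvas <- canvas + stats::rnorm(length(canvas), 0, noise_sd)
    matrix(as.integer(round(clamp(canvas, 0, 255))), nrow(canvas))
  })
}

#' Frame sequences
#'
#' A frame sequence couples a list of grayscale frames (integer matrices,
#' rows = y, cols = x, 0..255) with strictly increasing timestamps in
#' seconds. Inter-frame intervals may be non-uniform.
#'
#' @param frames List of integer matrices.
#' @param t Numeric vector of timestamps (seconds).
#' @return An object of class `frame_seq`.
#' @export
frame_seq <- function(frames, t) {
  stopifnot(length(frames) == length(t))
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, t = as.numeric(t)), class = "frame_seq")
}

#' @export
length.frame_seq <- function(x) length(x$frames)

#' Generate a synthetic arena recording with ground truth
#'
#' Renders a full arena frame sequence: one fly per programmed ROI moving
#' under its [behavior_program()], variable frame intervals drawn as
#' `(1/nominal_fps) * (1 + jitter * U(-1, 1))` (emulating the fluctuating
#' 1-5 FPS of real-time tracking), and additive pixel noise. Ground truth
#' (exact centroids in mm and px, per-frame state, per-window labels) is
#' returned alongside the frames.
#'
#' @param template An `arena_template`.
#' @param programs Named list of [behavior_program()]s, names = ROI indices;
#'   or a single program applied to one ROI (index 1).
#' @param duration_s Recording duration (seconds).
#' @param fps Nominal frame rate (frames per second, 1-5 for tracking-mode
#'   fixtures).
#' @param fps_jitter Relative jitter of inter-frame intervals in [0, 1).
#' @param noise_sd Gaussian pixel-noise SD.
#' @param seed Integer seed; the whole recording is a deterministic function
#'   of (template, programs, seed).
#' @param transform Arena placement; identity placement by default.
#' @return List with `frames` (a [frame_seq()]), `truth` (list of data
#'   frames: `positions` with one row per frame per fly, `windows` with
#'   per-window labels per ROI), `template`, `transform`.
#' @export
generate_arena_frames <- function(template, programs, duration_s, fps = 3,
                                  fps_jitter = 0.2, noise_sd = 5, seed = NULL,
                                  transform = identity_placement(template)) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (inherits(programs, "behavior_program")) programs <- list(`1` = programs)
  if (!length(programs)) stop("empty program set")
  if (is.null(names(programs)) || any(!nzchar(names(programs))))
    stop("programs must be a named list (names = ROI indices)")
  with_seed(seed, {
    # timestamps
    n_max <- ceiling(duration_s * fps * (1 + fps_jitter)) + 2L
    iv <- (1 / fps) * (1 + fps_jitter * stats::runif(n_max, -1, 1))
    tt <- c(0, cumsum(iv))
    tt <- tt[tt < duration_s - 1e-9]
    # trajectories (sub-seeded from the same stream => deterministic)
    trajs <- lapply(programs, function(pr)
      simulate_fly_trajectory(pr, template$tube_length_mm,
                              seed = sample.int(.Machine$integer.max, 1),
                              timestamps = tt))
    static <- render_static(template, transform)
    static_i <- matrix(as.integer(round(clamp(static, 0, 255))),
                       nrow(static))
    pool <- make_noise_pool(noise_sd)
    npx <- length(static_i)
    # noise can only clip if 6 SD reaches past the intensity range
    clip_needed <- !is.null(pool) &&
      (min(static_i) - 6 * noise_sd < 0 || max(static_i) + 6 * noise_sd > 255)
    s <- transform_scale(transform)
    roi_ids <- as.integer(names(programs))
    tmpl_idx <- match(roi_ids,
                      vapply(template$rois_mm, function(r) r$index,
                             numeric(1)))
    # precompute all fly centres in frame px
    n_fr <- length(tt)
    fly_px <- lapply(seq_along(roi_ids), function(j) {
      rt <- template$rois_mm[[tmpl_idx[j]]]
      p <- roi_local_to_template_mm(rt, trajs[[j]]$x_mm, trajs[[j]]$y_mm,
                                    template$tube_length_mm)
      apply_transform(transform, p)
    })
    axis_degs <- vapply(seq_along(roi_ids), function(j) {
      crn <- apply_transform(transform,
                             template$rois_mm[[tmpl_idx[j]]]$corners)
      ax <- crn[4, ] - crn[1, ]
      rad2deg(atan2(ax[2], ax[1]))
    }, numeric(1))
    a_px <- FLY_SEMI_AXES_MM[1] * s
    b_px <- FLY_SEMI_AXES_MM[2] * s
    h <- nrow(static_i); w <- ncol(static_i)
    frames <- vector("list", n_fr)
    for (k in seq_len(n_fr)) {
      if (is.null(pool)) {
        fr <- static_i
      } else {
        noise <- pool[floor(stats::runif(npx) * length(pool)) + 1L]
        fr <- static_i + noise
        if (clip_needed) fr <- clamp(fr, 0L, 255L)
        dim(fr) <- dim(static_i)
      }
      for (j in seq_along(roi_ids)) {
        cx <- fly_px[[j]][k, 1]; cy <- fly_px[[j]][k, 2]
        r <- a_px + 2
        x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
        y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
        if (x0 > x1 || y0 > y1) next
        patch <- draw_ellipse_px(static[(y0:y1) + 1, (x0:x1) + 1,
                                        drop = FALSE],
                                 cx - x0, cy - y0, a_px, b_px,
                                 axis_degs[j], INK_DARK)
        if (!is.null(pool))
          patch <- patch + (fr[(y0:y1) + 1, (x0:x1) + 1] -
                              static_i[(y0:y1) + 1, (x0:x1) + 1])
        fr[(y0:y1) + 1, (x0:x1) + 1] <-
          as.integer(round(clamp(patch, 0, 255)))
      }
      frames[[k]] <- fr
    }
    positions <- data.frame(
      frame = rep(seq_len(n_fr), each = length(roi_ids)),
      t = rep(tt, each = length(roi_ids)),
      roi = rep(roi_ids, n_fr),
      x_mm = as.vector(vapply(seq_len(n_fr), function(k)
        vapply(trajs, function(tr) tr$x_mm[k], numeric(1)),
        numeric(length(roi_ids)))),
      y_mm = as.vector(vapply(seq_len(n_fr), function(k)
        vapply(trajs, function(tr) tr$y_mm[k], numeric(1)),
        numeric(length(roi_ids)))),
      x_px = as.vector(vapply(seq_len(n_fr), function(k)
        vapply(seq_along(roi_ids), function(j) fly_px[[j]][k, 1],
               numeric(1)), numeric(length(roi_ids)))),
      y_px = as.vector(vapply(seq_len(n_fr), function(k)
        vapply(seq_along(roi_ids), function(j) fly_px[[j]][k, 2],
               numeric(1)), numeric(length(roi_ids)))),
      state = as.vector(vapply(seq_len(n_fr), function(k)
        vapply(trajs, function(tr) tr$state[k], character(1)),
        character(length(roi_ids)))),
      stringsAsFactors = FALSE)
    windows <- do.call(rbind, lapply(seq_along(roi_ids), function(j) {
      wl <- attr(trajs[[j]], "windows")
      if (!nrow(wl)) return(NULL)
      cbind(roi = roi_ids[j], wl)
    }))
    list(frames = frame_seq(frames, tt),
         truth = list(positions = positions, windows = windows),
         template = template, transform = transform)
  })
}
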
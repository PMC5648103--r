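#' Detect the arena's three fiducial marks
#'
#' Finds dark circular marks by Otsu thresholding and connected-component
#' labeling, scoring each candidate by how well its equivalent radius
#' matches `expected_radius_px` (within +/- 50%) and by roundness (the
#' square root of the ratio of its principal second moments, ~1 for a
#' circle). Centroids are refined with intensity weighting, which locates a
#' printed disc to a small fraction of a pixel. If more than three
#' candidates survive and a template is supplied, the triplet whose
#' side-length ratios best match the template's fiducial triangle is
#' returned; an unresolvable ambiguity raises `ambiguous_fiducials`.
#'
#' @param frame Grayscale frame (integer/numeric matrix, rows = y).
#' @param expected_radius_px Expected fiducial radius in pixels.
#' @param template Optional `arena_template` used to disambiguate when more
#'   than three candidates are found.
#' @param roundness_max Maximum admissible axis ratio (default 1.4; a fly
#'   body at ~2.5 is rejected).
#' @param ratio_tol Maximum summed mismatch of normalized triangle side
#'   lengths when matching a triplet against the template.
#' @return Data frame (class `fiducial_set`) with columns `x`, `y`
#'   (0-based px) and `score`, exactly 3 rows.
#' @export
detect_fiducials <- function(frame, expected_radius_px, template = NULL,
                             roundness_max = 1.4, ratio_tol = 0.05) {
  stopifnot(is.matrix(frame))
  m <- frame
  # the marks are high-contrast printed ink: threshold halfway between the
  # darkest pixel and the median background (robust against the bimodal
  # arena/tube background, which defeats a plain Otsu split)
  thr <- (stats::median(m) + min(m)) / 2
  bin <- m < thr
  if (!any(bin)) et_stop("no_fiducials", "no dark marks found in frame")
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- matrix(as.integer(lab), nrow(m))
  areas <- tabulate(lab[lab > 0])
  amin <- pi * (0.5 * expected_radius_px)^2
  amax <- pi * (1.5 * expected_radius_px)^2
  keep <- which(areas >= amin & areas <= amax)
  cand <- list()
  for (l in keep) {
    idx <- which(lab == l)
    yy <- (idx - 1) %% nrow(m)        # 0-based row = y
    xx <- (idx - 1) %/% nrow(m)       # 0-based col = x
    w <- pmax(thr - m[idx], 0)
    sw <- sum(w)
    if (sw <= 0) next
    cx <- sum(w * xx) / sw; cy <- sum(w * yy) / sw
    mxx <- sum(w * (xx - cx)^2) / sw
    myy <- sum(w * (yy - cy)^2) / sw
    mxy <- sum(w * (xx - cx) * (yy - cy)) / sw
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE,
                only.values = TRUE)$values
    round_ratio <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
    if (round_ratio > roundness_max) next
    r_eq <- sqrt(areas[l] / pi)
    score <- exp(-((r_eq / expected_radius_px - 1) / 0.25)^2) *
             exp(-((round_ratio - 1) / 0.2)^2)
    cand[[length(cand) + 1]] <- data.frame(x = cx, y = cy, score = score)
  }
  if (length(cand) < 3)
    et_stop("no_fiducials", "found %d circular mark(s), need 3", length(cand))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), , drop = FALSE]
  if (nrow(cand) > 3) {
    if (is.null(template)) {
      cand <- cand[1:3, ]
    } else {
      rt <- sort(triangle_opposite_sides(template$fiducials_mm))
      rt <- rt / sum(rt)
      combs <- utils::combn(nrow(cand), 3)
      mism <- apply(combs, 2, function(ix) {
        s <- sort(triangle_opposite_sides(as.matrix(cand[ix, c("x", "y")])))
        sum(abs(s / sum(s) - rt))
      })
      if (min(mism) > ratio_tol)
        et_stop("ambiguous_fiducials",
                "%d candidate marks, none of the triplets matches the template triangle",
                nrow(cand))
      cand <- cand[combs[, which.min(mism)], ]
    }
  }
  rownames(cand) <- NULL
  structure(cand, class = c("fiducial_set", "data.frame"))
}

#' Fit the template-to-image affine transform from 3 fiducials
#'
#' Puts detected and template fiducials in correspondence by ordering each
#' triangle's vertices by the length of the opposite side (the template
#' triangle must be scalene for this to be unambiguous), then solves the
#' exact three-point affine map.
#'
#' @param detected A `fiducial_set` or 3x2 matrix of detected centres (px).
#' @param template An `arena_template`.
#' @return An `affine2d` mapping template mm to image px.
#' @export
fit_arena_transform <- function(detected, template) {
  D <- if (is.data.frame(detected)) as.matrix(detected[, c("x", "y")])
       else matrix(as.numeric(detected), 3, 2)
  Tm <- template$fiducials_mm
  if (triangle_area(D) < 1e-6)
    et_stop("degenerate_geometry", "detected fiducials are collinear")
  ordD <- order(triangle_opposite_sides(D))
  ordT <- order(triangle_opposite_sides(Tm))
  D <- D[ordD, , drop = FALSE]
  Tm <- Tm[ordT, , drop = FALSE]
  X <- cbind(Tm, 1)
  A <- tryCatch(solve(X, D), error = function(e)
    et_stop("degenerate_geometry", "fiducial geometry is degenerate"))
  affine2d(t(A))
}

#' Map template ROIs into image coordinates
#'
#' @param template An `arena_template`.
#' @param transform An `affine2d` from [fit_arena_transform()].
#' @param frame_px Optional `c(width, height)`; ROIs whose corners fall
#'   outside are flagged `out_of_frame`.
#' @return List of `roi` objects: each has `index`, `corners` (4x2 px,
#'   template corner order preserved), `mm_per_px` (recomputed from the
#'   transform's scale), `food_center` and unit `axis`/`perp` vectors
#'   (axis points from the food end into the tube), `tube_length_mm`,
#'   `tube_width_mm`, an integer crop `bbox` and the `out_of_frame` flag.
#' @export
build_rois <- function(template, transform, frame_px = template$frame_px) {
  s <- transform_scale(transform)          # px per mm
  mm_per_px <- 1 / s
  pad_ax <- ceiling(FLY_SEMI_AXES_MM[1] * s) + 3
  pad_tr <- 3
  lapply(template$rois_mm, function(rt) {
    crn <- apply_transform(transform, rt$corners)
    food_idx <- if (identical(rt$food_end, "right")) c(3, 4) else c(1, 2)
    far_idx <- setdiff(1:4, food_idx)
    food_center <- colMeans(crn[food_idx, , drop = FALSE])
    far_center <- colMeans(crn[far_idx, , drop = FALSE])
    ax <- far_center - food_center
    ax <- ax / sqrt(sum(ax^2))
    pp <- c(-ax[2], ax[1])
    x0 <- floor(min(crn[, 1])) - pad_ax; x1 <- ceiling(max(crn[, 1])) + pad_ax
    y0 <- floor(min(crn[, 2])) - pad_tr; y1 <- ceiling(max(crn[, 2])) + pad_tr
    oof <- FALSE
    if (!is.null(frame_px)) {
      oof <- any(crn[, 1] < 0 | crn[, 1] > frame_px[1] - 1 |
                 crn[, 2] < 0 | crn[, 2] > frame_px[2] - 1)
      x0 <- max(x0, 0); y0 <- max(y0, 0)
      x1 <- min(x1, frame_px[1] - 1); y1 <- min(y1, frame_px[2] - 1)
    }
    structure(list(
      index = as.integer(rt$index), corners = crn, mm_per_px = mm_per_px,
      food_end = rt$food_end, food_center = food_center, axis = ax, perp = pp,
      tube_length_mm = template$tube_length_mm,
      tube_width_mm = template$tube_width_mm,
      bbox = as.integer(c(x0, y0, x1, y1)),
      pad_ax = pad_ax, pad_tr = pad_tr,
      out_of_frame = oof
    ), class = "roi")
  })
}

#' Convert frame px coordinates to ROI-local mm coordinates
#'
#' @param roi A `roi` object.
#' @param pts n x 2 matrix of 0-based pixel coordinates.
#' @return n x 2 matrix: `x_mm` from the food end along the tube axis,
#'   `y_mm` transverse.
#' @export
roi_local_mm <- function(roi, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  d <- sweep(pts, 2, roi$food_center)
  cbind(x_mm = (d %*% roi$axis) * roi$mm_per_px,
        y_mm = (d %*% roi$perp) * roi$mm_per_px)
}

#' One-shot arena registration
#'
#' Detects the fiducials in a frame, fits the affine placement and maps the
#' template ROIs into image coordinates. Registration is performed once on
#' the first frame of a recording and held fixed (the arena is static for
#' the duration of an experiment).
#'
#' @param frame Grayscale frame matrix.
#' @param template An `arena_template`.
#' @return List with `fiducials`, `transform` and `rois`.
#' @export
register_arena <- function(frame, template) {
  r_px <- template$fiducial_radius_mm / template$mm_per_px
  fid <- detect_fiducials(frame, r_px, template)
  tr <- fit_arena_transform(fid, template)
  rois <- build_rois(template, tr, frame_px = c(ncol(frame), nrow(frame)))
  list(fiducials = fid, transform = tr, rois = rois)
}
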
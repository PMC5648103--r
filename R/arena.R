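#' Arena templates and affine placements
#'
#' An arena template describes the physical geometry of a behavioral arena in
#' millimetre coordinates: three fiducial reference marks printed on the
#' arena, one rectangular region of interest (ROI) per fly tube, and the
#' nominal calibration used when the arena is imaged square-on. Registration
#' (see [detect_fiducials()]) maps this template into image pixels.
#'
#' Conventions: image origin at the top-left pixel, x rightward, y downward,
#' 0-based pixel indices; within a tube, position is reported in mm from the
#' food end along the tube axis.
#'
#' @param fiducials_mm 3x2 matrix of fiducial centres (mm). Must be
#'   non-collinear and scalene, so that the three-point correspondence with
#'   detected marks is unambiguous.
#' @param rois_mm List of ROIs; each a list with `index`, `corners` (4x2 mm,
#'   corners in order food-end-bottom, food-end-top, far-top, far-bottom)
#'   and `food_end` (`"left"` or `"right"`, which short side holds the food).
#' @param mm_per_px Nominal calibration (mm per pixel) at identity placement.
#' @param tube_length_mm,tube_width_mm Interior tube dimensions (mm).
#' @param fiducial_radius_mm Radius of the printed fiducial discs (mm).
#' @param margin_mm Blank margin around the arena when rendering (mm).
#' @return An object of class `arena_template`.
#' @export
arena_template <- function(fiducials_mm, rois_mm, mm_per_px,
                           tube_length_mm, tube_width_mm = 5,
                           fiducial_radius_mm = 1.5, margin_mm = 25) {
  fiducials_mm <- as.matrix(fiducials_mm)
  stopifnot(nrow(fiducials_mm) == 3, ncol(fiducials_mm) == 2,
            mm_per_px > 0, tube_length_mm > 0, length(rois_mm) >= 1)
  if (triangle_area(fiducials_mm) < 1e-6)
    et_stop("degenerate_geometry", "template fiducials are collinear")
  sides <- sort(triangle_opposite_sides(fiducials_mm))
  if (min(diff(sides)) / max(sides) < 0.02)
    warning("template fiducial triangle is nearly isosceles; ",
            "correspondence may be ambiguous")
  idx <- vapply(rois_mm, function(r) as.integer(r$index), integer(1))
  if (anyDuplicated(idx))
    stop("ROI indices must be unique within an arena")

  all_mm <- do.call(rbind, c(list(fiducials_mm),
                             lapply(rois_mm, function(r) as.matrix(r$corners))))
  lo <- apply(all_mm, 2, min) - margin_mm
  hi <- apply(all_mm, 2, max) + margin_mm
  origin_px <- -lo / mm_per_px
  frame_px <- ceiling((hi - lo) / mm_per_px)  # c(width, height)

  structure(list(
    fiducials_mm = fiducials_mm,
    rois_mm = rois_mm,
    mm_per_px = mm_per_px,
    tube_length_mm = tube_length_mm,
    tube_width_mm = tube_width_mm,
    fiducial_radius_mm = fiducial_radius_mm,
    margin_mm = margin_mm,
    frame_px = as.integer(frame_px),
    origin_px = origin_px
  ), class = "arena_template")
}

#' Standard sleep-arena template
#'
#' The stacked-tube sleep arena: `n_tubes` horizontal tubes (food end on the
#' left), three scalene fiducial discs outside the tube block. The default
#' 20-tube layout is the arena most commonly used for sleep studies.
#'
#' @param n_tubes Number of tubes (ROIs).
#' @param tube_length_mm,tube_width_mm Tube interior size in mm.
#' @param gap_mm Vertical gap between adjacent tubes.
#' @inheritParams arena_template
#' @return An `arena_template`.
#' @examples
#' tpl <- sleep_arena_template()
#' length(tpl$rois_mm)  # 20
#' @export
sleep_arena_template <- function(n_tubes = 20, tube_length_mm = 60,
                                 tube_width_mm = 5, gap_mm = 2,
                                 mm_per_px = 0.1, margin_mm = 25) {
  L <- tube_length_mm; W <- tube_width_mm
  rois <- lapply(seq_len(n_tubes), function(i) {
    y0 <- (i - 1) * (W + gap_mm)
    list(index = i,
         corners = rbind(c(0, y0), c(0, y0 + W), c(L, y0 + W), c(L, y0)),
         food_end = "left")
  })
  H <- (n_tubes - 1) * (W + gap_mm) + W
  fid <- rbind(c(-6, -6), c(L + 8, -9), c(-9, H + 7))
  arena_template(fid, rois, mm_per_px, L, W, margin_mm = margin_mm)
}

#' Read or write an arena template as JSON
#'
#' @param template An `arena_template`.
#' @param path File path.
#' @return `read_arena_template()` returns an `arena_template`;
#'   `write_arena_template()` returns `path` invisibly.
#' @export
write_arena_template <- function(template, path) {
  x <- list(
    fiducials_mm = template$fiducials_mm,
    rois_mm = lapply(template$rois_mm, function(r)
      list(index = r$index, corners = as.matrix(r$corners),
           food_end = r$food_end)),
    mm_per_px = template$mm_per_px,
    tube_length_mm = template$tube_length_mm,
    tube_width_mm = template$tube_width_mm,
    fiducial_radius_mm = template$fiducial_radius_mm,
    margin_mm = template$margin_mm
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arena_template
#' @export
read_arena_template <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rois <- lapply(x$rois_mm, function(r)
    list(index = r$index,
         corners = do.call(rbind, lapply(r$corners, unlist)),
         food_end = r$food_end))
  fid <- do.call(rbind, lapply(x$fiducials_mm, unlist))
  arena_template(fid, rois,
                 x$mm_per_px, x$tube_length_mm, x$tube_width_mm,
                 x$fiducial_radius_mm, x$margin_mm)
}

# ---- affine transforms (template mm -> image px) ---------------------------

#' Affine transforms between template and image coordinates
#'
#' A 2x3 matrix `M` mapping homogeneous template mm coordinates to image
#' pixel coordinates: `px = M %*% c(x_mm, y_mm, 1)`.
#'
#' @param M 2x3 numeric matrix.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(M) {
  M <- matrix(as.numeric(M), 2, 3)
  if (abs(det(M[, 1:2])) < 1e-12)
    et_stop("degenerate_geometry", "affine linear part is singular")
  structure(list(M = M), class = "affine2d")
}

#' @rdname affine2d
#' @param template An `arena_template`.
#' @export
identity_placement <- function(template) {
  s <- 1 / template$mm_per_px
  affine2d(cbind(diag(c(s, s)), template$origin_px))
}

#' Apply an affine transform to points
#'
#' @param transform An `affine2d`.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  t(transform$M %*% rbind(t(pts), 1))
}

#' Scale of an affine transform in px per mm
#' @param transform An `affine2d`.
#' @return Scalar px-per-mm scale (sqrt of |det| of the linear part).
#' @export
transform_scale <- function(transform) sqrt(abs(det(transform$M[, 1:2])))

#' Randomized arena placement for synthetic frames
#'
#' Composes the identity placement with a rotation about the arena centre and
#' a pixel translation, emulating the small pose variation of an arena slid
#' into its holder.
#'
#' @param template An `arena_template`.
#' @param rotation_deg Rotation in degrees (counter-clockwise in image axes).
#' @param translation_px Length-2 pixel translation.
#' @param scale Relative scale factor (1 = nominal calibration).
#' @return An `affine2d`.
#' @export
make_placement <- function(template, rotation_deg = 0,
                           translation_px = c(0, 0), scale = 1) {
  th <- deg2rad(rotation_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- scale / template$mm_per_px
  corners <- do.call(rbind, lapply(template$rois_mm, function(r) r$corners))
  c_mm <- colMeans(corners)
  c_px <- c_mm / template$mm_per_px + template$origin_px
  lin <- s * R
  off <- c_px + translation_px - lin %*% c_mm
  affine2d(cbind(lin, off))
}
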
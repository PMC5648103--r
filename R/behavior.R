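#' Frame-interval-corrected velocity
#'
#' For consecutive non-inferred track points the corrected velocity is
#' `v_corr(i) = (euclidean displacement in mm / body_length_mm) *
#' (dt_nominal / dt_i)`: a dimensionless "relative unit" equal to body
#' lengths per nominal interval, so a displacement of one body length
#' (2.5 mm) over one nominal interval gives exactly 1. With the default
#' `dt_nominal = 1` s the unit is body lengths per second, which makes the
#' movement (1.0) and walking (2.5) thresholds independent of the frame
#' rate. Carried-forward (inferred) points contribute zero displacement:
#' velocity across a detection gap is computed between the surrounding real
#' points, avoiding phantom speed from occlusions.
#'
#' @param traj A `trajectory` (needs `t`, `x_mm`, `y_mm`, `is_inferred`).
#' @param body_length_mm Body length (mm, default 2.5).
#' @param dt_nominal Nominal frame interval (seconds, default 1).
#' @return Data frame with one row per step between real points: `t` (step
#'   end), `dt`, `dist_mm`, `v_corr`.
#' @export
compute_velocity <- function(traj, body_length_mm = 2.5, dt_nominal = 1) {
  real <- traj[!traj$is_inferred, , drop = FALSE]
  if (nrow(real) < 2) stop("need >= 2 non-inferred points")
  if (any(diff(real$t) <= 0)) stop("timestamps must be strictly increasing")
  dt <- diff(real$t)
  dist <- sqrt(diff(real$x_mm)^2 + diff(real$y_mm)^2)
  data.frame(t = real$t[-1], dt = dt, dist_mm = dist,
             v_corr = (dist / body_length_mm) * (dt_nominal / dt))
}

#' Windowed movement features
#'
#' Tiles the trajectory with contiguous non-overlapping windows (nominal
#' 10 s, aligned to the trajectory start) and computes, per window, the
#' maximal corrected velocity and the cumulative walked distance (mm). A
#' window containing no velocity step has its features marked missing; the
#' classifier then inherits the previous window's label.
#'
#' @inheritParams compute_velocity
#' @param window_s Window length (seconds, default 10).
#' @return Data frame (class `feature_windows`): `window_start`,
#'   `window_end`, `max_velocity`, `cum_distance`, `n_points`,
#'   `has_inferred`, `missing`, `complete` (whether the window is fully
#'   inside the trajectory span).
#' @export
windowed_features <- function(traj, window_s = 10, body_length_mm = 2.5,
                              dt_nominal = 1) {
  t0 <- traj$t[1]
  span <- traj$t[nrow(traj)] - t0
  if (span < window_s) stop("trajectory spans less than one window")
  vel <- compute_velocity(traj, body_length_mm, dt_nominal)
  n_win <- max(1L, ceiling((span - 1e-9) / window_s))
  wi_pts <- pmin(floor((traj$t - t0) / window_s) + 1L, n_win)
  # a step is assigned to the window containing its end sample; a step
  # ending exactly on a boundary belongs to the later window, matching the
  # convention that a sample at the boundary opens the new window
  wi_step <- pmin(floor((vel$t - t0) / window_s) + 1L, n_win)
  out <- data.frame(
    window_start = t0 + (seq_len(n_win) - 1) * window_s,
    window_end = t0 + seq_len(n_win) * window_s,
    max_velocity = NA_real_, cum_distance = NA_real_,
    n_points = as.integer(tabulate(wi_pts, n_win)),
    has_inferred = as.logical(tabulate(wi_pts[traj$is_inferred], n_win)),
    missing = TRUE,
    complete = t0 + seq_len(n_win) * window_s <= traj$t[nrow(traj)] + 1e-9
  )
  if (nrow(vel)) {
    mx <- tapply(vel$v_corr, factor(wi_step, levels = seq_len(n_win)), max)
    cd <- tapply(vel$dist_mm, factor(wi_step, levels = seq_len(n_win)), sum)
    got <- !is.na(mx)
    out$max_velocity[got] <- mx[got]
    out$cum_distance[got] <- cd[got]
    out$missing <- !got
  }
  class(out) <- c("feature_windows", "data.frame")
  out
}

#' Three-state classification from maximal corrected velocity
#'
#' `max_velocity < t_move` is immobile, `t_move <= max_velocity < t_walk`
#' is micromovement, `>= t_walk` is walking (a value exactly at a threshold
#' is assigned upward). The defaults are the movement threshold 1.0 and the
#' walking threshold 2.5 in relative units.
#'
#' @param max_velocity Numeric vector of per-window maximal velocities.
#' @param t_move,t_walk Classification thresholds (relative units).
#' @return Character vector of labels.
#' @export
classify_window <- function(max_velocity, t_move = 1.0, t_walk = 2.5) {
  stopifnot(t_move > 0, t_walk > t_move)
  ifelse(is.na(max_velocity), NA_character_,
         ifelse(max_velocity < t_move, "immobile",
                ifelse(max_velocity < t_walk, "micromovement", "walking")))
}

#' @rdname classify_window
#' @param features A `feature_windows` data frame; windows with missing
#'   features inherit the previous window's label.
#' @return `classify_windows()` returns `features` with a `label` column.
#' @export
classify_windows <- function(features, t_move = 1.0, t_walk = 2.5) {
  lab <- classify_window(features$max_velocity, t_move, t_walk)
  for (i in seq_along(lab))
    if (is.na(lab[i]) && i > 1) lab[i] <- lab[i - 1]
  features$label <- lab
  features
}

#' Random-forest variable-importance feature screening
#'
#' Screens candidate window features for predictors of the behavioral state
#' using random-forest permutation variable importance (mean decrease in
#' out-of-bag accuracy when the feature is permuted; small negative values,
#' which are permutation noise around zero, are truncated to 0). The Gini
#' importance is reported alongside. Deterministic under a fixed seed.
#'
#' @param features Data frame or matrix, windows x features.
#' @param labels Behavior label per window.
#' @param seed Integer seed or `NULL`.
#' @param num_trees Number of trees.
#' @return Data frame ranked by decreasing importance, with attribute
#'   `total_importance`.
#' @export
rank_features <- function(features, labels, seed = NULL, num_trees = 500) {
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes to rank features")
  x <- as.data.frame(features)
  rf <- with_seed(seed,
    randomForest::randomForest(x = x, y = droplevels(y), ntree = num_trees,
                               importance = TRUE))
  imp <- pmax(rf$importance[, "MeanDecreaseAccuracy"], 0)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    gini = as.numeric(rf$importance[, "MeanDecreaseGini"]))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "total_importance") <- sum(out$importance)
  out
}

#' Consensus labels from multiple annotators
#'
#' Keeps a window's label only when a strict majority of its (at least
#' three) annotators agree; windows without a strict majority are excluded
#' as ambiguous.
#'
#' @param annotations Data frame with `window_id`, `annotator`, `label`.
#' @return Data frame with `window_id`, `n_annotators`, `consensus` (NA
#'   when excluded) and `excluded`.
#' @export
consensus_labels <- function(annotations) {
  sp <- split(annotations$label, annotations$window_id)
  bad <- names(sp)[vapply(sp, length, integer(1)) < 3]
  if (length(bad))
    stop("windows with < 3 annotations: ", paste(bad, collapse = ", "))
  rows <- lapply(names(sp), function(id) {
    tab <- table(sp[[id]])
    n <- length(sp[[id]])
    top <- max(tab)
    maj <- top > n / 2 && sum(tab == top) == 1
    data.frame(window_id = id, n_annotators = n,
               consensus = if (maj) names(tab)[which.max(tab)]
                           else NA_character_,
               excluded = !maj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class detection accuracy against consensus labels
#'
#' Per-class accuracy is the fraction of consensus windows of that class
#' that the classifier labeled correctly (class recall); windows excluded
#' as ambiguous are ignored.
#'
#' @param predicted Character vector of predicted labels, aligned with
#'   `truth`.
#' @param truth Either a character vector of consensus labels (NA =
#'   excluded) or the data frame from [consensus_labels()].
#' @return List with `confusion` (truth x predicted table), `per_class`
#'   (named accuracy vector) and `n`.
#' @export
score_classifier <- function(predicted, truth) {
  if (is.data.frame(truth)) truth <- truth$consensus
  if (length(predicted) != length(truth))
    stop("predicted and truth must be aligned")
  keep <- !is.na(truth)
  if (!any(keep)) stop("no non-excluded truth windows")
  lv <- c("immobile", "micromovement", "walking")
  tr <- factor(truth[keep], levels = lv)
  pr <- factor(predicted[keep], levels = lv)
  conf <- table(truth = tr, predicted = pr)
  per_class <- diag(conf) / rowSums(conf)
  list(confusion = conf, per_class = per_class, n = sum(keep))
}

#' Tracking discrepancy against annotated positions
#'
#' Matches tracked and annotated positions by timestamp and reports the
#' per-frame distance in micrometres, its median, and the fraction of
#' frames whose discrepancy exceeds one body length.
#'
#' @param predicted A `trajectory` (uses `x_mm`, `y_mm`).
#' @param annotated Data frame with `t` and either `x_mm`/`y_mm` or pixel
#'   `x`/`y` plus `mm_per_px`.
#' @param mm_per_px Calibration used when `annotated` is in pixels.
#' @param body_length_mm Body length (mm, default 2.5).
#' @param t_tol Timestamp matching tolerance (seconds).
#' @return List with `distances_um`, `median_um`,
#'   `fraction_exceeding_body_length`, `n_matched`.
#' @export
position_discrepancy <- function(predicted, annotated, mm_per_px = NULL,
                                 body_length_mm = 2.5, t_tol = 1e-6) {
  if (!all(c("x_mm", "y_mm") %in% names(annotated))) {
    if (is.null(mm_per_px))
      stop("mm_per_px required for pixel-coordinate annotations")
    annotated$x_mm <- annotated$x * mm_per_px
    annotated$y_mm <- annotated$y * mm_per_px
  }
  idx <- match(round(annotated$t / t_tol), round(predicted$t / t_tol))
  ok <- !is.na(idx)
  if (!any(ok)) stop("no frames matched by timestamp")
  d_mm <- sqrt((predicted$x_mm[idx[ok]] - annotated$x_mm[ok])^2 +
               (predicted$y_mm[idx[ok]] - annotated$y_mm[ok])^2)
  list(distances_um = d_mm * 1000,
       median_um = stats::median(d_mm) * 1000,
       fraction_exceeding_body_length = mean(d_mm > body_length_mm),
       n_matched = sum(ok))
}
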
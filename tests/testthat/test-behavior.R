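traj_df <- function(t, x_mm, y_mm = 0, inferred = FALSE) {
  data.frame(t = t, x_mm = x_mm, y_mm = rep(y_mm, length.out = length(t)),
             is_inferred = rep(inferred, length.out = length(t)))
}

test_that("corrected velocity is body-length- and interval-normalized", {
  # one body length (2.5 mm) over one nominal interval -> exactly 1
  v <- compute_velocity(traj_df(c(0, 1), c(0, 2.5)))
  expect_equal(v$v_corr, 1.0)
  # zero displacement -> 0
  expect_equal(compute_velocity(traj_df(c(0, 1), c(5, 5)))$v_corr, 0)
  # same displacement over twice the interval -> half the velocity
  v2 <- compute_velocity(traj_df(c(0, 2), c(0, 2.5)))
  expect_equal(v2$v_corr, 0.5)
  # inferred points contribute no displacement; velocity bridges real points
  tr <- traj_df(c(0, 1, 2), c(0, 50, 2.5), inferred = c(FALSE, TRUE, FALSE))
  expect_equal(compute_velocity(tr)$v_corr, 0.5)
  expect_error(compute_velocity(traj_df(c(0, 0), c(0, 1))), "increasing")
  expect_error(compute_velocity(traj_df(0, 0)), "2 non-inferred")
})

test_that("windowed features take the in-window max and cumulative distance", {
  t <- seq(0, 30, by = 1)
  x <- c(0, cumsum(rep(2.5, 30)))       # constant v_corr = 1
  fw <- windowed_features(traj_df(t, x))
  expect_equal(fw$max_velocity[1:3], rep(1, 3))
  # steps ending exactly on a boundary open the next window; the final
  # boundary step folds into the last window
  expect_equal(fw$cum_distance[1:3], c(22.5, 25, 27.5))
  expect_equal(sum(fw$cum_distance), 75)
  # a single spike dominates the max
  x2 <- c(0, cumsum(c(rep(0, 5), 12.5, rep(0, 24))))
  fw2 <- windowed_features(traj_df(t, x2))
  expect_equal(max(fw2$max_velocity, na.rm = TRUE), 5)
  # a window with no steps is flagged missing and inherits on classify
  t3 <- c(0, 1, 2, 25, 26, 30)
  fw3 <- windowed_features(traj_df(t3, rep(0, 6)))
  expect_true(fw3$missing[2])
  lab <- classify_windows(fw3)
  expect_equal(lab$label[2], lab$label[1])
})

test_that("thresholds classify the three states with upward boundary ties", {
  expect_equal(classify_window(0.5), "immobile")
  expect_equal(classify_window(1.7), "micromovement")
  expect_equal(classify_window(3.0), "walking")
  expect_equal(classify_window(1.0), "micromovement")  # boundary goes up
  expect_equal(classify_window(2.5), "walking")
})

test_that("raising thresholds only moves labels toward quieter classes", {
  set.seed(2)
  v <- runif(500, 0, 5)
  rank_of <- c(immobile = 1, micromovement = 2, walking = 3)
  base <- rank_of[classify_window(v)]
  for (tm in c(1.2, 1.6)) {
    up <- rank_of[classify_window(v, t_move = tm)]
    expect_true(all(up <= base))
  }
  for (tw in c(3, 4)) {
    up <- rank_of[classify_window(v, t_walk = tw)]
    expect_true(all(up <= base))
  }
})

test_that("feature screening ranks a separating feature first, is seed-stable, and stays flat on noise", {
  set.seed(10)
  n <- 300
  lab <- sample(c("immobile", "walking"), n, TRUE)
  sep <- ifelse(lab == "walking", 3, 0) + rnorm(n, 0, 0.2)
  noise <- rnorm(n)
  r <- rank_features(data.frame(sep = sep, noise = noise), lab, seed = 1)
  expect_equal(r$feature[1], "sep")
  expect_gt(r$importance[1], 5 * max(r$importance[2], 1e-6))
  expect_identical(rank_features(data.frame(sep = sep, noise = noise),
                                 lab, seed = 1), r)
  expect_error(rank_features(data.frame(a = rnorm(10)), rep("walking", 10)),
               "2 classes")
  # pure-noise features: no feature dominates across seeds (small additive
  # tolerance because permutation importances sit near zero)
  xn <- data.frame(a = rnorm(n), b = rnorm(n))
  for (s in 1:10) {
    rn <- rank_features(xn, lab, seed = s)
    expect_lt(max(rn$importance), 3 * min(rn$importance) + 0.05)
  }
})

test_that("consensus keeps strict majorities and excludes ambiguity", {
  ann <- data.frame(
    window_id = rep(c("w1", "w2", "w3"), each = 3),
    annotator = rep(1:3, 3),
    label = c("walking", "walking", "micromovement",
              "walking", "micromovement", "immobile",
              "immobile", "immobile", "immobile"))
  cs <- consensus_labels(ann)
  expect_equal(cs$consensus[cs$window_id == "w1"], "walking")
  expect_true(cs$excluded[cs$window_id == "w2"])
  expect_equal(cs$consensus[cs$window_id == "w3"], "immobile")
  expect_error(consensus_labels(ann[1:2, ]), "< 3 annotations")
})

test_that("scoring reports per-class detection accuracy from the confusion table", {
  truth <- c(rep("walking", 100), rep("micromovement", 50))
  pred <- truth
  pred[1:10] <- "micromovement"          # 90/100 walking correct
  sc <- score_classifier(pred, truth)
  expect_equal(unname(sc$per_class["walking"]), 0.9)
  expect_equal(unname(sc$per_class["micromovement"]), 1.0)
  expect_equal(sum(sc$confusion), 150)
  # perfect predictions: 100% everywhere present
  sc2 <- score_classifier(truth, truth)
  expect_true(all(sc2$per_class[c("walking", "micromovement")] == 1))
  expect_error(score_classifier(pred, rep(NA_character_, 150)),
               "non-excluded")
})

test_that("position discrepancy converts to micrometres and counts gross errors", {
  tr <- traj_df(0:9, seq(0, 9) * 1.0)
  same <- data.frame(t = 0:9, x_mm = tr$x_mm, y_mm = 0)
  d0 <- position_discrepancy(tr, same)
  expect_equal(d0$median_um, 0)
  expect_equal(d0$fraction_exceeding_body_length, 0)
  # a uniform 3 px offset at 0.1 mm/px is 300 um everywhere
  off <- data.frame(t = 0:9, x = (tr$x_mm + 0.3) / 0.1, y = 0)
  d1 <- position_discrepancy(tr, off, mm_per_px = 0.1)
  expect_equal(d1$distances_um, rep(300, 10))
  expect_equal(d1$median_um, 300)
  expect_equal(d1$fraction_exceeding_body_length, 0)
  expect_error(position_discrepancy(tr, data.frame(t = 100:105, x_mm = 0,
                                                   y_mm = 0)),
               "no frames matched")
})
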
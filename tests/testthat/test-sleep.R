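labels_of <- function(x) data.frame(window_start = (seq_along(x) - 1) * 10,
                                    label = x)

test_that("sleep bouts follow the five-minute immobility rule", {
  b <- annotate_sleep(labels_of(rep("immobile", 60)))       # 600 s
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 600)
  expect_equal(nrow(annotate_sleep(labels_of(rep("immobile", 20)))), 0)
  alt <- labels_of(rep(c("immobile", "walking"), 30))
  expect_equal(nrow(annotate_sleep(alt)), 0)
  # two runs split by one active window
  two <- labels_of(c(rep("immobile", 40), "walking", rep("immobile", 35)))
  b2 <- annotate_sleep(two)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$duration, c(400, 350))
})

test_that("sleep profiles bin bout coverage and conserve total bout time", {
  span <- c(0, 4 * 1800)
  bouts <- data.frame(start = c(0, 1800, 3600, 5400),
                      end = c(900, 2700, 4500, 6300))
  class(bouts) <- c("sleep_bouts", "data.frame")
  pr <- sleep_profile(bouts, bin_s = 1800, span = span)
  expect_equal(pr$fraction_asleep, rep(0.5, 4))   # first half of every bin
  full <- data.frame(start = 0, end = 7200)
  expect_equal(sleep_profile(full, 1800, span)$fraction_asleep, rep(1, 4))
  none <- data.frame(start = numeric(0), end = numeric(0))
  expect_equal(sleep_profile(none, 1800, span)$fraction_asleep, rep(0, 4))
  expect_error(sleep_profile(full, 0, span), "positive")
  # conservation, including bouts not aligned to bins
  set.seed(3)
  st <- sort(runif(6, 0, 6000)); en <- st + runif(6, 100, 600)
  en <- pmin(en, c(st[-1], 7200))                 # keep non-overlapping
  rb <- data.frame(start = st, end = en)
  pr2 <- sleep_profile(rb, 1800, span)
  expect_equal(sum(pr2$fraction_asleep) * 1800, sum(en - st),
               tolerance = 1e-9)
})

test_that("bootstrap CI is percentile-based, seeded and degenerate on constants", {
  same <- rep(4.2, 30)
  ci <- bootstrap_ci(same, n_boot = 200, seed = 1)
  expect_equal(ci$lower, 4.2)
  expect_equal(ci$upper, 4.2)
  set.seed(99); x <- rnorm(40)
  a <- bootstrap_ci(x, n_boot = 1000, seed = 7)
  b <- bootstrap_ci(x, n_boot = 1000, seed = 7)
  expect_identical(a, b)
  expect_lt(a$lower, mean(x)); expect_gt(a$upper, mean(x))
  expect_error(bootstrap_ci(1), ">= 2")
})

test_that("stimulus counts aggregate per individual with sample SD", {
  ev <- data.frame(t = c(1, 2, 3, 10, 11, 12, 20, 21, 22, 23, 24, 25),
                   roi = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 3, 3))
  cs <- count_stimuli(ev, rois = 1:3)
  expect_equal(unname(cs$counts), c(2, 4, 6))
  expect_equal(cs$mean, 4)
  expect_equal(cs$sd, 2)
  none <- count_stimuli(ev[0, ], rois = 1:3)
  expect_equal(unname(none$counts), c(0, 0, 0))
  expect_equal(none$sd, 0)
  win <- count_stimuli(ev, window = c(100, 200), rois = 1:3)
  expect_true(all(win$counts == 0))
})

test_that("rebound quantification runs pairwise Wilcoxon and excludes dead flies", {
  set.seed(4)
  d <- data.frame(group = rep(c("A", "B"), each = 10),
                  fly = rep(1:10, 2),
                  minutes = c(rnorm(10, 1, 1e-4), rnorm(10, 2, 1e-4)))
  rq <- rebound_quantification(d)
  expect_lt(rq$p_values["B", "A"], 0.001)
  # identical groups: statistic at its null centre
  d2 <- d; d2$minutes <- rep(5, 20)
  rq2 <- rebound_quantification(d2)
  expect_gt(rq2$p_values["B", "A"], 0.9)
  # dead flies reduce n before testing
  d$alive <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 10))
  rq3 <- rebound_quantification(d)
  expect_equal(rq3$n, c(8, 10))
  expect_error(rebound_quantification(d[d$group == "A", ]), "2 groups")
})

test_that("wilcoxon p-values match exact enumeration for small n", {
  set.seed(12)
  for (nn in list(c(4, 5), c(6, 6))) {
    x <- rnorm(nn[1]); y <- rnorm(nn[2], 0.8)
    p_pkg <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, enumerate_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("whiskers follow Tukey's 1.5 IQR rule on fixed vectors", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 50)
  w <- tukey_whiskers(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  expect_equal(w$lower, min(x[x >= q[1] - 1.5 * iqr]))
  expect_equal(w$upper, max(x[x <= q[2] + 1.5 * iqr]))
  expect_equal(w$outliers, 50)
  expect_equal(w$median, median(x))
  # no outliers: whiskers reach the extremes
  y <- 1:11
  wy <- tukey_whiskers(y)
  expect_equal(wy$lower, 1); expect_equal(wy$upper, 11)
  expect_length(wy$outliers, 0)
})

test_that("sleep minutes inside a window clip bouts to the window", {
  b <- data.frame(start = c(0, 500), end = c(400, 1100))
  expect_equal(sleep_minutes_in(b, c(0, 1200)), 1000 / 60)
  expect_equal(sleep_minutes_in(b, c(300, 600)), 200 / 60)
  expect_equal(sleep_minutes_in(b[0, ], c(0, 100)), 0)
})

test_that("plot helpers return ggplot objects with ribbon and boxplot layers", {
  prof <- matrix(runif(60), nrow = 6)
  p1 <- plot_sleep_profile(prof, bin_s = 1800, n_boot = 50, seed = 1)
  expect_s3_class(p1, "ggplot")
  d <- data.frame(group = rep(c("a", "b"), each = 5), minutes = runif(10))
  p2 <- plot_rebound(d)
  expect_s3_class(p2, "ggplot")
})
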
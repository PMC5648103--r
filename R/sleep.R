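#' Annotate sleep bouts from windowed behavior labels
#'
#' Sleep is scored with the standard immobility criterion: a maximal run of
#' contiguous `immobile` windows whose total duration reaches
#' `min_sleep_s` (default 300 s, the five-minute rule) becomes one sleep
#' bout.
#'
#' @param labels Data frame with `window_start` and `label` for contiguous
#'   equal-length windows, or a character vector of labels.
#' @param window_s Window length (seconds); inferred from `window_start`
#'   when omitted and derivable.
#' @param min_sleep_s Minimum immobility run to count as sleep (seconds).
#' @param t0 Start time when `labels` is a bare vector.
#' @return Data frame (class `sleep_bouts`) with `start`, `end`,
#'   `duration`.
#' @export
annotate_sleep <- function(labels, window_s = NULL, min_sleep_s = 300,
                           t0 = 0) {
  if (is.data.frame(labels)) {
    lab <- labels$label
    starts <- labels$window_start
    if (is.null(window_s))
      window_s <- if (length(starts) > 1) starts[2] - starts[1] else 10
  } else {
    lab <- as.character(labels)
    if (is.null(window_s)) window_s <- 10
    starts <- t0 + (seq_along(lab) - 1) * window_s
  }
  r <- rle(lab == "immobile" & !is.na(lab))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- r$values & r$lengths * window_s >= min_sleep_s
  out <- data.frame(start = starts[starts_idx[keep]],
                    end = starts[ends_idx[keep]] + window_s,
                    duration = r$lengths[keep] * window_s)
  class(out) <- c("sleep_bouts", "data.frame")
  out
}

#' Binned sleep profile
#'
#' Fraction of each bin (default 30 minutes) covered by sleep bouts.
#' Conservation holds exactly: the summed `fraction * bin_s` over bins
#' equals the total bout time inside the span.
#'
#' @param bouts A `sleep_bouts` data frame.
#' @param bin_s Bin width (seconds, default 1800 = 30 min).
#' @param span Length-2 experiment interval (seconds).
#' @return Data frame with `bin_start` and `fraction_asleep` in [0, 1].
#' @export
sleep_profile <- function(bouts, bin_s = 1800, span) {
  if (bin_s <= 0) stop("bin width must be positive")
  edges <- seq(span[1], span[2], by = bin_s)
  if (edges[length(edges)] < span[2]) edges <- c(edges, span[2])
  n_bin <- length(edges) - 1
  frac <- numeric(n_bin)
  for (b in seq_len(n_bin)) {
    lo <- edges[b]; hi <- edges[b + 1]
    if (nrow(bouts)) {
      ov <- pmin(bouts$end, hi) - pmax(bouts$start, lo)
      frac[b] <- sum(pmax(ov, 0)) / (hi - lo)
    }
  }
  data.frame(bin_start = edges[-length(edges)], fraction_asleep = frac)
}

#' Percentile bootstrap confidence band over individuals
#'
#' Resamples individuals (rows) with replacement and returns the percentile
#' confidence interval of the cross-individual mean; the field-standard way
#' to ribbon a population sleep profile.
#'
#' @param x Numeric vector (one value per individual) or matrix
#'   (individuals x bins).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed or `NULL`.
#' @return List with `mean`, `lower`, `upper` (vectors of length = number
#'   of columns; scalars for vector input) and `n`.
#' @export
bootstrap_ci <- function(x, n_boot = 5000, level = 0.95, seed = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) stop("need >= 2 individuals")
  a <- (1 - level) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    boots <- apply(x, 2, function(col) {
      bm <- colMeans(matrix(col[idx], nrow = n))
      stats::quantile(bm, c(a, 1 - a), names = FALSE, type = 7)
    })
    list(mean = colMeans(x), lower = boots[1, ], upper = boots[2, ], n = n)
  })
}

#' Count stimuli per individual
#'
#' @param events Event data frame (`t`, `roi`) from [run_closed_loop()].
#' @param window Optional length-2 interval restricting the count.
#' @param rois ROI universe (so zero-count individuals are included).
#' @return List with `counts` (named per ROI), `mean` and `sd` (sample SD
#'   across individuals).
#' @export
count_stimuli <- function(events, window = NULL, rois = NULL) {
  ev <- events
  if (!is.null(window))
    ev <- ev[ev$t >= window[1] & ev$t < window[2], , drop = FALSE]
  if (is.null(rois)) rois <- sort(unique(events$roi))
  if (!length(rois)) rois <- 1L
  counts <- vapply(rois, function(r) sum(ev$roi == r), numeric(1))
  names(counts) <- rois
  list(counts = counts, mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0)
}

#' Quantify sleep rebound with pairwise Wilcoxon tests
#'
#' Computes each individual's minutes of sleep inside a window (typically
#' the first 3 h after the stimulation period) and compares groups with
#' pairwise two-sided Wilcoxon rank-sum tests. Individuals flagged dead are
#' excluded before testing.
#'
#' @param sleep_minutes Data frame with `group`, `fly`, `minutes` and
#'   optionally `alive` (logical).
#' @param p_adjust Multiplicity adjustment passed to
#'   [stats::pairwise.wilcox.test()] (default `"none"`).
#' @return List with `per_fly` (the filtered input), `p_values` (matrix of
#'   pairwise p-values) and `n` per group.
#' @export
rebound_quantification <- function(sleep_minutes, p_adjust = "none") {
  d <- sleep_minutes
  if ("alive" %in% names(d)) d <- d[d$alive, , drop = FALSE]
  ns <- table(d$group)
  if (length(ns) < 2) stop("need >= 2 groups")
  if (any(ns < 2)) stop("every group needs >= 2 flies")
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(d$minutes, factor(d$group),
                                p.adjust.method = p_adjust))
  p <- pw$p.value
  # zero-variance comparisons (all values tied) have the statistic at its
  # null centre; the tie-corrected normal approximation degenerates to NaN
  p[is.nan(p)] <- 1
  list(per_fly = d, p_values = p, n = as.vector(ns))
}

#' Minutes asleep inside a window
#'
#' @param bouts A `sleep_bouts` data frame.
#' @param window Length-2 interval (seconds).
#' @return Minutes of bout time overlapping the window.
#' @export
sleep_minutes_in <- function(bouts, window) {
  if (!nrow(bouts)) return(0)
  ov <- pmin(bouts$end, window[2]) - pmax(bouts$start, window[1])
  sum(pmax(ov, 0)) / 60
}

#' Tukey boxplot whiskers
#'
#' Whisker endpoints under Tukey's rule: the most extreme data values
#' within 1.5 IQR of the hinges (first and third quartiles).
#'
#' @param x Numeric vector.
#' @return List with `hinges`, `median`, `lower`, `upper`, `outliers`.
#' @export
tukey_whiskers <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[2] + 1.5 * iqr
  list(hinges = q,
       median = stats::median(x),
       lower = min(x[x >= lo_fence]),
       upper = max(x[x <= hi_fence]),
       outliers = x[x < lo_fence | x > hi_fence])
}
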
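#' Plot a population sleep profile with a bootstrap ribbon
#'
#' Draws the cross-individual mean fraction asleep per bin with the
#' percentile-bootstrap confidence band, the standard way population sleep
#' time courses are shown.
#'
#' @param profiles Numeric matrix, individuals x bins, of per-bin fraction
#'   asleep (rows aligned; e.g. stacked [sleep_profile()] outputs).
#' @param bin_s Bin width in seconds.
#' @param n_boot,level,seed Passed to [bootstrap_ci()].
#' @return A ggplot object.
#' @export
plot_sleep_profile <- function(profiles, bin_s = 1800, n_boot = 1000,
                               level = 0.95, seed = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sleep_profile needs the ggplot2 package")
  ci <- bootstrap_ci(profiles, n_boot = n_boot, level = level, seed = seed)
  d <- data.frame(t_h = (seq_len(ncol(profiles)) - 1) * bin_s / 3600,
                  mean = ci$mean, lower = ci$lower, upper = ci$upper)
  ggplot2::ggplot(d, ggplot2::aes(x = t_h, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "fraction asleep") +
    ggplot2::theme_minimal()
}

#' Tukey boxplots of per-fly sleep amounts by group
#'
#' Whiskers follow Tukey's rule (most extreme values within 1.5 IQR of the
#' hinges), matching [tukey_whiskers()].
#'
#' @param sleep_minutes Data frame with `group` and `minutes` (e.g. the
#'   `rebound` table from [simulate_sleep_experiment()]).
#' @return A ggplot object.
#' @export
plot_rebound <- function(sleep_minutes) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_rebound needs the ggplot2 package")
  ggplot2::ggplot(sleep_minutes, ggplot2::aes(x = group, y = minutes)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "sleep (min)") +
    ggplot2::theme_minimal()
}
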
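#' Behavior programs for the synthetic fly
#'
#' A behavior program is an ordered list of segments, each a duration in
#' seconds spent in one of the three behavioral states: `immobile`,
#' `micromovement` or `walking`. Each state carries a kinematic model in the
#' dimensionless velocity unit used by the classifier (body lengths per
#' second, corrected for the frame interval; see [compute_velocity()]), so
#' that the realized per-window maximal velocity is consistent with the
#' segment's class by construction:
#'
#' * `immobile`: small in-place jitter, `|N(0.2, 0.1)|`.
#' * `micromovement`: intermittent in-place activity (grooming, eating):
#'   with a per-bout burst probability drawn from `burst_p = c(0.4, 0.7)`,
#'   each step is either a burst from `N(1.75, 0.2)` or quiescent jitter
#'   `|N(0.15, 0.1)|`.
#' * `walking`: stop-and-go locomotion: strides from `N(4.5, 0.5)` at a
#'   per-bout probability drawn from `burst_p = c(0.4, 0.8)`, pauses
#'   otherwise. Intermittency and bout-to-bout vigor variation are
#'   deliberate: one stride is enough to make a window "walking" by
#'   maximal velocity, while the window's cumulative distance can remain
#'   modest — which is why maximal velocity, not cumulative distance, is
#'   the faithful predictor of the behavioral state.
#'
#' All distributions sit at least 3 SD inside the classification bands
#' delimited by the movement (1.0) and walking (2.5) thresholds.
#'
#' @param states Character vector of segment states.
#' @param durations_s Numeric vector of segment durations (seconds, > 0).
#' @param kinematics Optional list overriding the per-state kinematics; see
#'   [default_kinematics()].
#' @return An object of class `behavior_program`.
#' @export
behavior_program <- function(states, durations_s,
                             kinematics = default_kinematics()) {
  states <- as.character(states)
  ok <- states %in% c("immobile", "micromovement", "walking")
  if (!all(ok))
    stop("invalid state name(s): ", paste(unique(states[!ok]), collapse = ", "))
  if (length(states) != length(durations_s) || !length(states))
    stop("states and durations_s must be non-empty and of equal length")
  if (any(durations_s <= 0))
    stop("segment durations must be positive")
  for (s in unique(states)) {
    mu <- kinematics[[s]]$mean
    if (s == "immobile" && mu >= 1)
      stop("immobile mean velocity must be < 1")
    if (s == "micromovement" && (mu <= 1 || mu >= 2.5))
      stop("micromovement mean velocity must lie in (1, 2.5)")
    if (s == "walking" && mu <= 2.5)
      stop("walking mean velocity must be > 2.5")
  }
  structure(list(states = states, durations_s = as.numeric(durations_s),
                 kinematics = kinematics),
            class = "behavior_program")
}

#' @rdname behavior_program
#' @export
default_kinematics <- function() {
  list(
    immobile      = list(mean = 0.2,  sd = 0.1, burst_p = c(1, 1),
                         base_mean = 0.2,  base_sd = 0.1),
    micromovement = list(mean = 1.75, sd = 0.2, burst_p = c(0.4, 0.7),
                         base_mean = 0.15, base_sd = 0.1),
    walking       = list(mean = 4.5,  sd = 0.5, burst_p = c(0.4, 0.8),
                         base_mean = 0.15, base_sd = 0.1)
  )
}

#' Random behavior program with window-aligned segments
#'
#' Draws a sequence of state segments whose durations are multiples of the
#' classification window, so ground-truth window labels are unambiguous.
#'
#' @param duration_s Total program duration (seconds).
#' @param seed Integer seed or `NULL`.
#' @param segment_choices_s Candidate segment durations (seconds).
#' @param states States to draw from.
#' @return A `behavior_program` of total duration >= `duration_s`.
#' @export
random_behavior_program <- function(duration_s, seed = NULL,
                                    segment_choices_s = seq(10, 60, by = 10),
                                    states = c("immobile", "micromovement",
                                               "walking")) {
  with_seed(seed, {
    segs <- character(0); durs <- numeric(0); tot <- 0
    while (tot < duration_s) {
      s <- sample(states, 1)
      # avoid back-to-back identical states so labels change at boundaries
      if (length(segs) && s == segs[length(segs)]) next
      d <- sample(segment_choices_s, 1)
      segs <- c(segs, s); durs <- c(durs, d); tot <- tot + d
    }
    behavior_program(segs, durs)
  })
}

# State of the program at given times (seconds from program start).
program_state_at <- function(program, t) {
  edges <- cumsum(program$durations_s)
  idx <- findInterval(t, c(0, edges), rightmost.closed = FALSE)
  idx <- clamp(idx, 1, length(program$states))
  program$states[idx]
}

#' Per-window ground-truth labels of a behavior program
#'
#' Labels each contiguous window by the state occupying the majority of the
#' window (ties broken by the state at the window start).
#'
#' @param program A `behavior_program`.
#' @param duration_s Span to label.
#' @param window_s Window length (seconds, default 10).
#' @return Data frame with `window_start` and `label`.
#' @export
program_window_labels <- function(program, duration_s, window_s = 10) {
  if (duration_s < window_s)
    return(data.frame(window_start = numeric(0), label = character(0)))
  starts <- seq(0, duration_s - window_s, by = window_s)
  lab <- vapply(starts, function(w0) {
    tt <- seq(w0, w0 + window_s, length.out = 21)
    mid <- (tt[-1] + tt[-length(tt)]) / 2
    st <- program_state_at(program, mid)
    tab <- table(st)
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1) best else program_state_at(program, w0)
  }, character(1))
  data.frame(window_start = starts, label = lab, stringsAsFactors = FALSE)
}

#' Simulate a single-fly trajectory inside a tube
#'
#' Simulates one fly's position along a tube under a [behavior_program()].
#' Motion is along the tube axis (mm from the food end) with a small
#' mean-reverting transverse jitter. Per step, a velocity `v` is drawn from
#' the current state's kinematics and the axial displacement is
#' `v * body_length_mm * dt`, so the realized corrected velocity equals `v`
#' by construction. Walking flies keep a persistent direction that reflects
#' at the tube ends; immobile and micromoving flies oscillate about an
#' anchor point.
#'
#' @param program A `behavior_program`.
#' @param tube_length_mm Tube length (mm).
#' @param seed Integer seed or `NULL`.
#' @param timestamps Frame times (seconds). If `NULL`, uniform at `fps`.
#' @param fps Nominal frame rate used when `timestamps` is `NULL`.
#' @param body_length_mm Fly body length (mm, default 2.5).
#' @param transverse_sd Transverse jitter velocity SD (relative units).
#' @param init_x_mm Initial axial position; default drawn away from the ends.
#' @return Data frame (class `fly_trajectory`) with `t`, `x_mm`, `y_mm`,
#'   `state`; attribute `windows` holds per-window ground-truth labels.
#' @examples
#' pr <- behavior_program("walking", 60)
#' tr <- simulate_fly_trajectory(pr, 60, seed = 1)
#' range(tr$x_mm)  # confined to [0, 60]
#' @export
simulate_fly_trajectory <- function(program, tube_length_mm, seed = NULL,
                                    timestamps = NULL, fps = 2,
                                    body_length_mm = 2.5,
                                    transverse_sd = 0.05,
                                    init_x_mm = NULL) {
  stopifnot(inherits(program, "behavior_program"))
  total <- sum(program$durations_s)
  if (is.null(timestamps))
    timestamps <- seq(0, total - 1 / fps, by = 1 / fps)
  n <- length(timestamps)
  with_seed(seed, {
    L <- tube_length_mm
    x <- numeric(n); y <- numeric(n)
    x[1] <- init_x_mm %||% stats::runif(1, min(5, L / 4), L - min(5, L / 4))
    y[1] <- 0
    states <- program_state_at(program, timestamps)
    anchor <- x[1]
    dir <- sample(c(-1, 1), 1)
    k0 <- program$kinematics[[states[1]]]
    p_burst <- stats::runif(1, min(k0$burst_p), max(k0$burst_p))
    for (i in seq_len(n)[-1]) {
      dt <- timestamps[i] - timestamps[i - 1]
      st <- states[i]
      k <- program$kinematics[[st]]
      if (st != states[i - 1]) {
        # bout onset: re-anchor in-place states, redraw the bout's vigor
        if (st != "walking") anchor <- x[i - 1]
        p_burst <- stats::runif(1, min(k$burst_p), max(k$burst_p))
      }
      burst <- stats::runif(1) < p_burst
      v <- if (burst) stats::rnorm(1, k$mean, k$sd)
           else abs(stats::rnorm(1, k$base_mean, k$base_sd))
      v <- max(v, 0)
      step <- v * body_length_mm * dt
      if (st == "walking") {
        if (stats::runif(1) < 0.05) dir <- -dir
        xn <- x[i - 1] + dir * step
        if (xn > L) { xn <- L; dir <- -1 }
        if (xn < 0) { xn <- 0; dir <- 1 }
      } else {
        d <- if (abs(x[i - 1] - anchor) < 1e-9) sample(c(-1, 1), 1)
             else -sign(x[i - 1] - anchor)
        xn <- clamp(x[i - 1] + d * step, 0, L)
      }
      x[i] <- xn
      y[i] <- clamp(0.8 * y[i - 1] +
                      stats::rnorm(1, 0, transverse_sd * body_length_mm * dt),
                    -1.5, 1.5)
    }
    out <- data.frame(t = timestamps, x_mm = x, y_mm = y, state = states,
                      stringsAsFactors = FALSE)
    attr(out, "windows") <- program_window_labels(program,
                                                  max(timestamps) + 1e-9)
    attr(out, "body_length_mm") <- body_length_mm
    class(out) <- c("fly_trajectory", "data.frame")
    out
  })
}
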
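#' Combinatorial trigger predicates
#'
#' A trigger is a predicate tree over position, time and behavior, evaluated
#' once per processed frame against the live track of one ROI. Leaves:
#'
#' * `trg_behavior_is(state, min_duration_s)`: the fly has been in `state`
#'   continuously for at least `min_duration_s` (every sample in the
#'   trailing interval is in `state` and the run started at least
#'   `min_duration_s` ago).
#' * `trg_position_within(min_mm, max_mm)`: the current position, measured
#'   in mm from the food end along the tube axis, lies in the zone.
#' * `trg_position_crossed(boundary)`: the most recent step crossed the
#'   boundary (`"midline"` = half the tube length, or an explicit mm
#'   coordinate). A strict side change is required: landing exactly on the
#'   boundary and retreating to the same side is not a crossing.
#' * `trg_time_in(windows)`: the experiment time lies in one of the
#'   scheduling windows (matrix of `start, end` rows, seconds).
#'
#' Combinators `trg_and()`, `trg_or()`, `trg_not()` compose leaves by
#' boolean algebra.
#'
#' @param state One of `immobile`, `micromovement`, `walking`.
#' @param min_duration_s Required continuous duration (seconds, >= 0).
#' @param min_mm,max_mm Zone limits (mm from the food end).
#' @param boundary `"midline"` or a coordinate in mm from the food end.
#' @param windows Numeric matrix (or list of length-2 vectors) of
#'   non-overlapping `start, end` times in seconds.
#' @param ... Sub-predicates.
#' @param x A sub-predicate.
#' @return A `trigger_predicate`.
#' @examples
#' # micromovement for >= 20 s within 5 mm of the food
#' trg_and(trg_behavior_is("micromovement", 20), trg_position_within(0, 5))
#' @export
trg_behavior_is <- function(state, min_duration_s) {
  if (!state %in% c("immobile", "micromovement", "walking"))
    stop("unknown behavior state: ", state)
  if (min_duration_s < 0) stop("min_duration_s must be >= 0")
  structure(list(op = "behavior_is", state = state,
                 min_duration_s = as.numeric(min_duration_s)),
            class = "trigger_predicate")
}

#' @rdname trg_behavior_is
#' @export
trg_position_within <- function(min_mm, max_mm) {
  if (max_mm < min_mm) stop("max_mm must be >= min_mm")
  structure(list(op = "position_within", min_mm = as.numeric(min_mm),
                 max_mm = as.numeric(max_mm)),
            class = "trigger_predicate")
}

#' @rdname trg_behavior_is
#' @export
trg_position_crossed <- function(boundary = "midline") {
  if (!identical(boundary, "midline")) boundary <- as.numeric(boundary)
  structure(list(op = "position_crossed", boundary = boundary),
            class = "trigger_predicate")
}

#' @rdname trg_behavior_is
#' @export
trg_time_in <- function(windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2)
  structure(list(op = "time_in", windows = windows),
            class = "trigger_predicate")
}

#' @rdname trg_behavior_is
#' @export
trg_and <- function(...)
  structure(list(op = "and", args = list(...)), class = "trigger_predicate")

#' @rdname trg_behavior_is
#' @export
trg_or <- function(...)
  structure(list(op = "or", args = list(...)), class = "trigger_predicate")

#' @rdname trg_behavior_is
#' @export
trg_not <- function(x)
  structure(list(op = "not", args = list(x)), class = "trigger_predicate")

#' Canned triggers: sleep deprivation and yoked control
#'
#' The sleep-deprivation trigger fires after sustained immobility (default
#' 20 consecutive seconds); the yoked-control trigger fires on midline
#' crossing, so the control arm is stimulated only while actually walking,
#' equalizing stimulus exposure without depriving sleep.
#'
#' @param min_immobile_s Immobility duration (seconds).
#' @return A `trigger_predicate`.
#' @export
sleep_deprivation_trigger <- function(min_immobile_s = 20)
  trg_behavior_is("immobile", min_immobile_s)

#' @rdname sleep_deprivation_trigger
#' @export
yoked_trigger <- function() trg_position_crossed("midline")

# ---- JSON mini-grammar ------------------------------------------------------

#' Parse and serialize trigger predicates (JSON mini-grammar)
#'
#' Triggers are exchanged as JSON objects with a single key naming the node:
#' `{"behavior_is": {"state": "immobile", "min_duration_s": 300}}`,
#' `{"position_within": {"min_mm": 0, "max_mm": 5}}`,
#' `{"position_crossed": {"boundary": "midline"}}`,
#' `{"time_in": {"windows": [[start, end], ...]}}`,
#' `{"and": [...]}` / `{"or": [...]}` / `{"not": {...}}`.
#' `parse_trigger(serialize_trigger(p))` returns a tree equal to `p`.
#'
#' @param text JSON string (or path to a JSON file).
#' @param tube_length_mm If given, zones and numeric boundaries are
#'   validated against the tube length.
#' @param pred A `trigger_predicate`.
#' @return `parse_trigger()` a `trigger_predicate`; `serialize_trigger()` a
#'   JSON string.
#' @export
parse_trigger <- function(text, tube_length_mm = NULL) {
  x <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("trigger parse error: ", conditionMessage(e)))
  build <- function(node) {
    if (!is.list(node) || length(node) != 1 || is.null(names(node)))
      stop("trigger parse error: each node must have exactly one key")
    op <- names(node)
    a <- node[[1]]
    switch(op,
      behavior_is = trg_behavior_is(a$state, a$min_duration_s),
      position_within = {
        p <- trg_position_within(a$min_mm, a$max_mm)
        if (!is.null(tube_length_mm) &&
            (a$min_mm < 0 || a$max_mm > tube_length_mm))
          stop("zone outside tube [0, ", tube_length_mm, "]")
        p
      },
      position_crossed = {
        b <- a$boundary
        if (!identical(b, "midline") && !is.null(tube_length_mm) &&
            (b < 0 || b > tube_length_mm))
          stop("boundary outside tube")
        trg_position_crossed(b)
      },
      time_in = trg_time_in(lapply(a$windows, unlist)),
      and = do.call(trg_and, lapply(a, build)),
      or = do.call(trg_or, lapply(a, build)),
      not = trg_not(build(a)),
      stop("unknown trigger leaf: ", op))
  }
  build(x)
}

#' @rdname parse_trigger
#' @export
serialize_trigger <- function(pred) {
  enc <- function(p) {
    switch(p$op,
      behavior_is = list(behavior_is = list(state = p$state,
                                            min_duration_s = p$min_duration_s)),
      position_within = list(position_within = list(min_mm = p$min_mm,
                                                    max_mm = p$max_mm)),
      position_crossed = list(position_crossed = list(boundary = p$boundary)),
      time_in = list(time_in = list(
        windows = lapply(seq_len(nrow(p$windows)),
                         function(i) p$windows[i, ]))),
      and = list(and = lapply(p$args, enc)),
      or = list(or = lapply(p$args, enc)),
      not = list(not = enc(p$args[[1]])))
  }
  as.character(jsonlite::toJSON(enc(pred), auto_unbox = TRUE, digits = NA))
}

# ---- evaluation -------------------------------------------------------------

resolve_boundary <- function(boundary, tube_length_mm) {
  if (identical(boundary, "midline")) {
    if (is.null(tube_length_mm))
      stop("tube_length_mm needed to resolve the midline")
    tube_length_mm / 2
  } else as.numeric(boundary)
}

#' Evaluate a trigger against a recorded history (reference semantics)
#'
#' Full re-scan evaluation of a predicate at time `t_now` over a recorded
#' history of per-frame samples. This is the reference evaluator; the
#' incremental [trigger_stepper()] used in the closed loop must agree with
#' it exactly.
#'
#' @param pred A `trigger_predicate`.
#' @param history Data frame with `t`, `state`, `x_mm`, sorted by `t`.
#' @param t_now Evaluation time; samples with `t <= t_now` are visible.
#' @param tube_length_mm Tube length, needed for `"midline"` boundaries.
#' @return Logical. An empty history evaluates to `FALSE`, never errors.
#' @export
evaluate_trigger <- function(pred, history, t_now,
                             tube_length_mm = NULL) {
  h <- history[history$t <= t_now + 1e-12, , drop = FALSE]
  n <- nrow(h)
  if (!n) return(FALSE)
  ev <- function(p) {
    switch(p$op,
      behavior_is = {
        if (h$state[n] != p$state) return(FALSE)
        j <- n
        while (j > 1 && h$state[j - 1] == p$state) j <- j - 1
        h$t[n] - h$t[j] >= p$min_duration_s - 1e-12
      },
      position_within = h$x_mm[n] >= p$min_mm && h$x_mm[n] <= p$max_mm,
      position_crossed = {
        b <- resolve_boundary(p$boundary, tube_length_mm)
        sides <- sign(h$x_mm - b)
        cur <- sides[n]
        if (cur == 0 || n < 2) return(FALSE)
        prevs <- sides[seq_len(n - 1)]
        prevs <- prevs[prevs != 0]
        length(prevs) > 0 && prevs[length(prevs)] == -cur
      },
      time_in = any(p$windows[, 1] <= h$t[n] & h$t[n] < p$windows[, 2]),
      and = all(vapply(p$args, ev, logical(1))),
      or = any(vapply(p$args, ev, logical(1))),
      not = !ev(p$args[[1]]))
  }
  ev(pred)
}

#' Incremental trigger evaluation for the real-time loop
#'
#' `trigger_stepper()` compiles a predicate into a stateful evaluator fed
#' one sample per processed frame; `step_trigger()` returns whether the
#' predicate holds at that sample, and `reset_trigger()` clears all
#' continuity clocks (used after a stimulus and its masking window, when
#' the immobility clock restarts).
#'
#' @param pred A `trigger_predicate`.
#' @param tube_length_mm Tube length for `"midline"` boundaries.
#' @return `trigger_stepper()` returns a stepper object (environment).
#' @export
trigger_stepper <- function(pred, tube_length_mm = NULL) {
  compile_node <- function(p) {
    switch(p$op,
      behavior_is = {
        e <- new.env(parent = emptyenv())
        e$run_start <- NA_real_
        list(step = function(t, state, x_mm) {
               if (identical(state, p$state)) {
                 if (is.na(e$run_start)) e$run_start <- t
                 t - e$run_start >= p$min_duration_s - 1e-12
               } else {
                 e$run_start <- NA_real_
                 FALSE
               }
             },
             reset = function() e$run_start <- NA_real_)
      },
      position_within = list(
        step = function(t, state, x_mm)
          x_mm >= p$min_mm && x_mm <= p$max_mm,
        reset = function() NULL),
      position_crossed = {
        b <- resolve_boundary(p$boundary, tube_length_mm)
        e <- new.env(parent = emptyenv())
        e$last_side <- 0
        list(step = function(t, state, x_mm) {
               cur <- sign(x_mm - b)
               fired <- cur != 0 && e$last_side != 0 && cur == -e$last_side
               if (cur != 0) e$last_side <- cur
               fired
             },
             reset = function() e$last_side <- 0)
      },
      time_in = list(
        step = function(t, state, x_mm)
          any(p$windows[, 1] <= t & t < p$windows[, 2]),
        reset = function() NULL),
      and = {
        ch <- lapply(p$args, compile_node)
        list(step = function(t, state, x_mm) {
               v <- vapply(ch, function(c) c$step(t, state, x_mm), logical(1))
               all(v)
             },
             reset = function() for (c in ch) c$reset())
      },
      or = {
        ch <- lapply(p$args, compile_node)
        list(step = function(t, state, x_mm) {
               v <- vapply(ch, function(c) c$step(t, state, x_mm), logical(1))
               any(v)
             },
             reset = function() for (c in ch) c$reset())
      },
      not = {
        ch <- compile_node(p$args[[1]])
        list(step = function(t, state, x_mm) !ch$step(t, state, x_mm),
             reset = function() ch$reset())
      })
  }
  st <- compile_node(pred)
  structure(list(step = st$step, reset = st$reset, predicate = pred),
            class = "trigger_stepper")
}

#' @rdname trigger_stepper
#' @param stepper A `trigger_stepper`.
#' @param t,state,x_mm The current sample.
#' @return `step_trigger()` a logical; `reset_trigger()` the stepper,
#'   invisibly.
#' @export
step_trigger <- function(stepper, t, state, x_mm)
  stepper$step(t, state, x_mm)

#' @rdname trigger_stepper
#' @export
reset_trigger <- function(stepper) {
  stepper$reset()
  invisible(stepper)
}

in_schedule <- function(t, schedule) {
  if (is.null(schedule)) return(TRUE)
  if (is.list(schedule)) schedule <- do.call(rbind, schedule)
  any(schedule[, 1] <= t & t < schedule[, 2])
}

#' Run a behavior-triggered closed loop over a recorded stream
#'
#' Replays a time-ordered stream of per-frame samples through a trigger.
#' When the trigger fires inside the armed schedule, a stimulus event is
#' emitted and the following `mask_s` seconds are masked: samples strictly
#' inside `(t_fire, t_fire + mask_s]` are suppressed (no track points, no
#' trigger evaluation — masking avoids motion artefacts from the stimulus
#' itself), and the continuity clocks restart after the mask.
#'
#' @param stream Data frame with `t`, `state`, `x_mm`, time-ordered.
#' @param trigger A `trigger_predicate`.
#' @param schedule Optional arming schedule: matrix or list of
#'   `start, end` rows (seconds); `NULL` = always armed.
#' @param stimulus Stimulus kind recorded on events (metadata only; the
#'   default rotation is parameterized at 60 degrees in 0.12 s).
#' @param stimulus_params Parameter string logged with each event.
#' @param mask_s Masking duration after each stimulus (seconds, default 5).
#' @param roi ROI index recorded on events.
#' @param tube_length_mm Tube length for `"midline"` boundaries.
#' @return List with `events` (data frame `t`, `roi`, `kind`), `stream`
#'   (the unmasked samples) and `masked` (the suppressed samples).
#' @export
run_closed_loop <- function(stream, trigger, schedule = NULL,
                            stimulus = "rotate", mask_s = 5, roi = 1L,
                            tube_length_mm = NULL,
                            stimulus_params = "angle_deg=60,duration_s=0.12") {
  st <- trigger_stepper(trigger, tube_length_mm)
  n <- nrow(stream)
  masked <- logical(n)
  ev_t <- numeric(0)
  mask_until <- -Inf
  for (i in seq_len(n)) {
    t <- stream$t[i]
    if (t <= mask_until + 1e-12) {
      masked[i] <- TRUE
      next
    }
    fired <- st$step(t, stream$state[i], stream$x_mm[i])
    if (fired && in_schedule(t, schedule)) {
      ev_t <- c(ev_t, t)
      mask_until <- t + mask_s
      st$reset()
    }
  }
  events <- data.frame(t = ev_t,
                       roi = rep(as.integer(roi), length(ev_t)),
                       kind = rep(stimulus, length(ev_t)),
                       params = rep(stimulus_params, length(ev_t)),
                       stringsAsFactors = FALSE)
  list(events = events,
       stream = stream[!masked, , drop = FALSE],
       masked = stream[masked, , drop = FALSE])
}
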
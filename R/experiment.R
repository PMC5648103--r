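#' Homeostatic virtual-fly model parameters
#'
#' A minimal two-process sleep model driving the three-arm
#' sleep-deprivation design: sleep pressure accumulates while awake
#' (`r_up` per hour), discharges during immobile rest (`r_down` per hour),
#' and modulates the per-tick probabilities of falling asleep and waking
#' together with the light-dark cycle (12 h:12 h). Awake flies walk, make
#' micromovements or sit still briefly; a stimulus (tube rotation) arouses
#' the fly, forcing it awake and walking.
#'
#' @param r_up,r_down Pressure accumulation/discharge rates (per hour).
#'   Pressure discharges only during consolidated sleep (a bout at least
#'   `consolidated_s` long): fragmented micro-sleeps are not restorative,
#'   which is what makes trigger-based sleep fragmentation a deprivation.
#' @param consolidated_s Minimum bout length before sleep discharges
#'   pressure (seconds; default 300, the sleep-scoring criterion).
#' @param p_max Pressure ceiling.
#' @param sleep_gain,sleep_theta Logistic gain and threshold of the
#'   fall-asleep probability in pressure units.
#' @param dark_sleep_bonus,light_sleep_penalty Additive logit shifts of the
#'   fall-asleep probability in dark/light.
#' @param wake_base,wake_pressure_slope,light_wake_bonus Logit terms of the
#'   per-tick wake probability.
#' @param awake_probs Probabilities of (walking, micromovement, immobile)
#'   while awake.
#' @param walk_step_mm Per-tick position change while walking (mm).
#' @return List of model parameters.
#' @export
fly_model_params <- function(r_up = 1.5, r_down = 4, p_max = 20,
                             consolidated_s = 300,
                             sleep_gain = 0.8, sleep_theta = 8,
                             dark_sleep_bonus = 2, light_sleep_penalty = 1.5,
                             wake_base = -3, wake_pressure_slope = 0.25,
                             light_wake_bonus = 1.5,
                             awake_probs = c(0.6, 0.25, 0.15),
                             walk_step_mm = 20) {
  list(r_up = r_up, r_down = r_down, p_max = p_max,
       consolidated_s = consolidated_s,
       sleep_gain = sleep_gain, sleep_theta = sleep_theta,
       dark_sleep_bonus = dark_sleep_bonus,
       light_sleep_penalty = light_sleep_penalty,
       wake_base = wake_base, wake_pressure_slope = wake_pressure_slope,
       light_wake_bonus = light_wake_bonus,
       awake_probs = awake_probs, walk_step_mm = walk_step_mm)
}

# One virtual fly under one experimental arm. Returns per-tick labels,
# stimulus times and positions. The closed-loop triggers are evaluated with
# the engine's sample semantics (immobility run clock, last-nonzero-side
# midline crossing, post-stimulus clock reset); at 10-s ticks the 5-s mask
# never covers a full tick, so masking suppresses no samples here.
simulate_one_fly <- function(arm, hours, tick_s, stim_schedule_s,
                             trigger_immobile_s, tube_length_mm, model) {
  n <- floor(hours * 3600 / tick_s)
  tt <- (seq_len(n) - 1) * tick_s
  light <- (tt / 3600) %% 24 < 12
  P <- stats::runif(1, 0, 2)
  asleep <- FALSE
  x <- stats::runif(1, 5, tube_length_mm - 5)
  dir <- sample(c(-1, 1), 1)
  states <- character(n)
  stim_t <- numeric(0)
  sleep_run <- 0L           # consecutive asleep ticks (consolidation)
  run_start <- NA_real_     # immobility clock (trigger engine semantics)
  last_side <- 0            # midline-crossing memory
  forced_awake <- 0L        # ticks of stimulus-driven arousal left
  mid <- tube_length_mm / 2
  for (i in seq_len(n)) {
    t <- tt[i]
    # sleep/wake transition
    if (forced_awake > 0L) {
      asleep <- FALSE
    } else if (asleep) {
      p_wake <- stats::plogis(model$wake_base -
                                model$wake_pressure_slope * P +
                                if (light[i]) model$light_wake_bonus else 0)
      if (stats::runif(1) < p_wake) asleep <- FALSE
    } else {
      p_sleep <- stats::plogis(model$sleep_gain * (P - model$sleep_theta) +
                                 if (light[i]) -model$light_sleep_penalty
                                 else model$dark_sleep_bonus)
      if (stats::runif(1) < p_sleep) asleep <- TRUE
    }
    # state and pressure: only consolidated sleep discharges pressure
    if (asleep) {
      st <- "immobile"
      sleep_run <- sleep_run + 1L
      if (sleep_run * tick_s >= model$consolidated_s)
        P <- max(0, P - model$r_down * tick_s / 3600)
    } else {
      st <- if (forced_awake > 0L) "walking"
            else sample(c("walking", "micromovement", "immobile"), 1,
                        prob = model$awake_probs)
      sleep_run <- 0L
      P <- min(model$p_max, P + model$r_up * tick_s / 3600)
    }
    if (forced_awake > 0L) forced_awake <- forced_awake - 1L
    states[i] <- st
    # position
    if (st == "walking") {
      if (stats::runif(1) < 0.2) dir <- -dir
      x <- x + dir * stats::runif(1, 0.5, 1) * model$walk_step_mm
      if (x > tube_length_mm) { x <- tube_length_mm; dir <- -1 }
      if (x < 0) { x <- 0; dir <- 1 }
    }
    # triggers (armed only inside the stimulation schedule)
    armed <- t >= stim_schedule_s[1] && t < stim_schedule_s[2]
    fired <- FALSE
    if (arm == "deprived") {
      if (st == "immobile") {
        if (is.na(run_start)) run_start <- t
        fired <- t - run_start >= trigger_immobile_s - 1e-9
      } else run_start <- NA_real_
    } else if (arm == "yoked") {
      cur <- sign(x - mid)
      fired <- cur != 0 && last_side != 0 && cur == -last_side
      if (cur != 0) last_side <- cur
    }
    if (fired && armed) {
      stim_t <- c(stim_t, t)
      run_start <- NA_real_
      forced_awake <- 2L
      asleep <- FALSE
    }
  }
  list(labels = data.frame(window_start = tt, label = states,
                           stringsAsFactors = FALSE),
       stimuli = stim_t)
}

#' Simulate the three-arm closed-loop sleep-deprivation design
#'
#' Simulates cohorts of homeostatic virtual flies under three arms run from
#' the same model: `deprived` (tube rotation triggered by 20 s of
#' immobility during the 12-h night stimulation window), `yoked` (rotation
#' triggered by the fly's own midline crossing, so stimuli arrive only
#' while walking) and `mock` (never stimulated). Sleep is scored with the
#' 5-minute immobility rule and rebound is quantified as minutes asleep in
#' the first `rebound_h` hours after the stimulation window.
#'
#' @param n_flies Flies per arm.
#' @param seed Integer seed.
#' @param hours Total simulated time (default 27: one baseline day, one
#'   stimulation night, a 3-h morning rebound window).
#' @param tick_s Simulation tick = behavior window length (seconds).
#' @param stim_start_h,stim_end_h Stimulation window (hours from start).
#' @param rebound_h Rebound quantification window length (hours).
#' @param trigger_immobile_s Immobility duration of the deprivation
#'   trigger (seconds).
#' @param tube_length_mm Tube length (mm).
#' @param model [fly_model_params()].
#' @return List with `rebound` (data frame `group`, `fly`, `minutes`),
#'   `stimuli` (data frame `group`, `fly`, `n_stimuli`), `labels` (per-arm
#'   list of per-fly label frames) and the windows used.
#' @export
simulate_sleep_experiment <- function(n_flies = 20, seed = NULL, hours = 27,
                                      tick_s = 10, stim_start_h = 12,
                                      stim_end_h = 24, rebound_h = 3,
                                      trigger_immobile_s = 20,
                                      tube_length_mm = 60,
                                      model = fly_model_params()) {
  arms <- c("deprived", "yoked", "mock")
  stim_win <- c(stim_start_h, stim_end_h) * 3600
  reb_win <- c(stim_end_h, stim_end_h + rebound_h) * 3600
  with_seed(seed, {
    reb <- list(); stim <- list(); labels <- list()
    for (arm in arms) {
      flies <- lapply(seq_len(n_flies), function(f)
        simulate_one_fly(arm, hours, tick_s, stim_win,
                         trigger_immobile_s, tube_length_mm, model))
      mins <- vapply(flies, function(fl) {
        bouts <- annotate_sleep(fl$labels, window_s = tick_s)
        sleep_minutes_in(bouts, reb_win)
      }, numeric(1))
      reb[[arm]] <- data.frame(group = arm, fly = seq_len(n_flies),
                               minutes = mins, stringsAsFactors = FALSE)
      stim[[arm]] <- data.frame(group = arm, fly = seq_len(n_flies),
                                n_stimuli = vapply(flies, function(fl)
                                  length(fl$stimuli), numeric(1)),
                                stringsAsFactors = FALSE)
      labels[[arm]] <- lapply(flies, function(fl) fl$labels)
    }
    list(rebound = do.call(rbind, reb),
         stimuli = do.call(rbind, stim),
         labels = labels,
         stim_window_s = stim_win, rebound_window_s = reb_win)
  })
}
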
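test_that("trigger JSON round-trips and rejects malformed specs", {
  p1 <- trg_behavior_is("immobile", 300)
  p2 <- trg_and(trg_behavior_is("micromovement", 20),
                trg_position_within(0, 5))
  p3 <- trg_or(trg_not(trg_position_crossed("midline")),
               trg_time_in(rbind(c(0, 43200))))
  for (p in list(p1, p2, p3))
    expect_equal(parse_trigger(serialize_trigger(p)), p)
  expect_error(parse_trigger("{not json"), "parse error")
  expect_error(parse_trigger('{"levitate": {}}'), "unknown trigger leaf")
  expect_error(parse_trigger(
    '{"behavior_is": {"state": "immobile", "min_duration_s": -5}}'),
    ">= 0")
  expect_error(parse_trigger(
    '{"position_within": {"min_mm": 0, "max_mm": 70}}',
    tube_length_mm = 60), "outside tube")
})

test_that("reference evaluation honors continuity, zones and empty histories", {
  h <- data.frame(t = 0:30,
                  state = c(rep("walking", 6), rep("immobile", 25)),
                  x_mm = 10)
  # immobile for 25 s, predicate >= 20 s -> true
  expect_true(evaluate_trigger(trg_behavior_is("immobile", 20), h, 30))
  # one micromovement sample 10 s ago breaks continuity
  h2 <- h; h2$state[21] <- "micromovement"
  expect_false(evaluate_trigger(trg_behavior_is("immobile", 20), h2, 30))
  # fly at 10 mm, zone within 5 mm of food -> false
  expect_false(evaluate_trigger(trg_position_within(0, 5), h, 30))
  # empty history is false for any predicate, never an error
  empty <- h[0, ]
  expect_false(evaluate_trigger(trg_behavior_is("immobile", 0), empty, 10))
  expect_false(evaluate_trigger(trg_not(trg_position_within(0, 60)),
                                empty, 10))
})

test_that("incremental stepper matches the reference evaluator on random predicates", {
  set.seed(5)
  leaves <- list(trg_behavior_is("immobile", 20),
                 trg_behavior_is("walking", 10),
                 trg_position_within(0, 5),
                 trg_position_crossed("midline"),
                 trg_time_in(rbind(c(50, 150))))
  mk <- function(d) {
    if (d == 1) return(leaves[[sample.int(length(leaves), 1)]])
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") trg_not(mk(d - 1))
    else do.call(paste0("trg_", op), list(mk(d - 1), mk(d - 1)))
  }
  for (r in 1:25) {
    pred <- mk(sample(1:3, 1))
    h <- data.frame(
      t = cumsum(runif(150, 0.5, 1.5)),
      state = sample(c("immobile", "micromovement", "walking"), 150, TRUE,
                     prob = c(0.5, 0.2, 0.3)),
      x_mm = sample(seq(0, 60, length.out = 10), 150, TRUE))
    st <- trigger_stepper(pred, 60)
    for (i in seq_len(150)) {
      expect_identical(step_trigger(st, h$t[i], h$state[i], h$x_mm[i]),
                       evaluate_trigger(pred, h[seq_len(i), ], h$t[i], 60))
    }
  }
})

test_that("closed loop fires, masks and reschedules as specified", {
  stream <- data.frame(t = 0:300,
                       state = ifelse(0:300 < 100, "walking", "immobile"),
                       x_mm = 30)
  cl <- run_closed_loop(stream, sleep_deprivation_trigger(20), mask_s = 5)
  expect_equal(cl$events$t[1], 120)
  # no track points survive inside (120, 125]
  expect_false(any(cl$stream$t > 120 & cl$stream$t <= 125))
  expect_true(all(cl$masked$t > 120))
  # masking exclusion holds for every event
  for (te in cl$events$t)
    expect_false(any(cl$stream$t > te & cl$stream$t <= te + 5))
  # schedule limits events to the armed window
  sched <- rbind(c(0, 150))
  cl2 <- run_closed_loop(stream, sleep_deprivation_trigger(20),
                         schedule = sched)
  expect_true(all(cl2$events$t < 150))
  cl3 <- run_closed_loop(stream, sleep_deprivation_trigger(20),
                         schedule = rbind(c(1e4, 2e4)))
  expect_equal(nrow(cl3$events), 0)
})

test_that("closed-loop event count equals the independent re-scan oracle", {
  stream <- data.frame(t = 0:1200, state = "immobile", x_mm = 30)
  cl <- run_closed_loop(stream, sleep_deprivation_trigger(20), mask_s = 5)
  oracle <- naive_closed_loop(stream, sleep_deprivation_trigger(20),
                              mask_s = 5)
  expect_identical(cl$events$t, oracle$event_t)
  # and on a jittered mixed stream with a schedule
  set.seed(8)
  s2 <- data.frame(t = cumsum(runif(400, 0.4, 1.2)),
                   state = sample(c("immobile", "walking"), 400, TRUE,
                                  prob = c(0.8, 0.2)),
                   x_mm = cumsum(rnorm(400, 0, 3)) %% 60)
  trig <- trg_and(trg_behavior_is("immobile", 10),
                  trg_position_within(0, 40))
  sched <- rbind(c(20, 200), c(250, 320))
  a <- run_closed_loop(s2, trig, schedule = sched, mask_s = 5,
                       tube_length_mm = 60)
  b <- naive_closed_loop(s2, trig, schedule = sched, mask_s = 5,
                         tube_length_mm = 60)
  expect_identical(a$events$t, b$event_t)
})

test_that("yoked trigger fires on strict midline crossings only", {
  st <- trigger_stepper(yoked_trigger(), tube_length_mm = 25)
  expect_false(step_trigger(st, 0, "walking", 11))
  expect_true(step_trigger(st, 1, "walking", 14))    # 11 -> 14 crosses 12.5
  # oscillation on one side never fires
  st2 <- trigger_stepper(yoked_trigger(), tube_length_mm = 25)
  fired <- vapply(seq(0, 20), function(i)
    step_trigger(st2, i, "walking", 1 + 4 * (i %% 2)), logical(1))
  expect_false(any(fired))
  # landing exactly on the midline and retreating is not a crossing
  st3 <- trigger_stepper(yoked_trigger(), tube_length_mm = 25)
  expect_false(step_trigger(st3, 0, "walking", 11))
  expect_false(step_trigger(st3, 1, "walking", 12.5))
  expect_false(step_trigger(st3, 2, "walking", 11))
})
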
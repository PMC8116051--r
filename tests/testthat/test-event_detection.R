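test_that("estimate_background pools nonselecting timepoints", {
  # constant 0.675 traces reproduce the reference background exactly
  ns <- stack_tracks(
    trace_track(rep(0.675, 6), track_id = "n1", condition = "nonselecting"),
    trace_track(rep(0.675, 9), track_id = "n2", condition = "nonselecting"))
  expect_equal(estimate_background(compute_ratio(ns)), 0.675)

  # timepoint-weighted mean: (0.6, 0.6) and (0.7, 0.7, 0.7) -> 0.66
  ns2 <- stack_tracks(
    trace_track(c(0.6, 0.6), track_id = "n1", condition = "nonselecting"),
    trace_track(c(0.7, 0.7, 0.7), track_id = "n2", condition = "nonselecting"))
  expect_equal(estimate_background(compute_ratio(ns2)), 0.66)

  # single constant trace
  one <- trace_track(rep(0.5, 4), condition = "nonselecting")
  expect_equal(estimate_background(compute_ratio(one)), 0.5)

  # per-run scope returns one value per run
  ns3 <- stack_tracks(
    trace_track(rep(0.6, 5), track_id = "n1", run_id = "A",
                condition = "nonselecting"),
    trace_track(rep(0.7, 5), track_id = "n2", run_id = "B",
                condition = "nonselecting"))
  expect_equal(estimate_background(compute_ratio(ns3), scope = "per_run"),
               c(A = 0.6, B = 0.7))

  # selecting-only input is an estimation error telling the caller to supply B
  sel <- trace_track(rep(0.7, 4), condition = "selecting")
  expect_error(estimate_background(compute_ratio(sel)), "supply")
})

test_that("detect_events reproduces the hand-worked hysteresis cases", {
  # trigger at the first of two consecutive >= B + 0.2; end at the first of
  # two consecutive < B + 0.1; duration 30 s at 10 s frames
  tt <- trace_track(c(0.60, 0.85, 0.85, 0.90, 0.65, 0.65, 0.60))
  ev <- run_detection(tt, background = 0.6)$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 1L)
  expect_equal(ev$end_frame, 4L)
  expect_true(ev$complete)
  expect_equal(ev$duration_s, 30)

  # a trace that never reaches B + delta_high yields nothing
  low <- trace_track(c(0.60, 0.75, 0.79, 0.60))
  expect_equal(nrow(run_detection(low, background = 0.6)$events), 0L)

  # track ending while signaling: incomplete event, no end, no duration
  trunc <- trace_track(c(0.60, 0.60, 0.85, 0.85))
  ev <- run_detection(trunc, background = 0.6)$events
  expect_equal(nrow(ev), 1L)
  expect_false(ev$complete)
  expect_true(is.na(ev$end_frame))
  expect_true(is.na(ev$duration_s))

  # non-finite ratios are rejected
  nf <- compute_ratio(trace_track(c(0.6, 0.9, 0.9)))
  nf$ratio[2] <- NaN
  expect_error(detect_events(nf, detection_params(background = 0.6)),
               "non-finite")
})

test_that("detect_events agrees with the brute-force oracle on random traces", {
  set.seed(101)
  det <- detection_params(background = 0.675)
  for (i in 1:250) {
    n <- sample(5:200, 1L)
    r <- random_trace(n)
    ev <- detect_events(compute_ratio(trace_track(r)), det)
    orc <- oracle_hysteresis(r, 0.675)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(orc)) {
      expect_equal(ev$start_frame, orc$start - 1L)
      expect_equal(ev$end_frame, orc$end - 1L)
    }
  }
})

test_that("event structure invariants hold on random traces", {
  set.seed(102)
  det <- detection_params(background = 0.675)
  B <- 0.675
  for (i in 1:80) {
    r <- random_trace(sample(20:150, 1L))
    ev <- detect_events(compute_ratio(trace_track(r)), det)
    if (nrow(ev) < 1L) next
    # ordered and non-overlapping
    expect_true(all(diff(ev$start_frame) > 0))
    comp <- ev[ev$complete, ]
    if (nrow(comp)) {
      expect_true(all(comp$end_frame > comp$start_frame))
      # r >= B + dh at start; r < B + dl at end and end + 1 (0-based frames)
      expect_true(all(r[comp$start_frame + 1L] >= B + 0.2))
      expect_true(all(r[comp$end_frame + 1L] < B + 0.1))
      expect_true(all(r[comp$end_frame + 2L] < B + 0.1))
    }
    if (nrow(ev) > 1L)
      expect_true(all(ev$start_frame[-1L] > ev$end_frame[-nrow(ev)]))
  }
})

test_that("raising delta_high never increases the event count", {
  set.seed(103)
  for (i in 1:40) {
    r <- random_trace(sample(30:150, 1L))
    tr <- compute_ratio(trace_track(r))
    counts <- vapply(c(0.15, 0.2, 0.25, 0.3), function(dh) {
      nrow(detect_events(tr, detection_params(background = 0.675,
                                              delta_high = dh)))
    }, numeric(1L))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("first_complete_event_durations applies the first-event rule", {
  # two complete events (30 s then 50 s): only the first contributes
  r <- c(0.6, 0.85, 0.85, 0.9, 0.65, 0.65, 0.6, 0.85, 0.85, 0.85, 0.85, 0.9,
         0.65, 0.65)
  ev <- run_detection(trace_track(r), background = 0.6)$events
  expect_equal(nrow(ev), 2L)
  dur <- first_complete_event_durations(ev)
  expect_equal(nrow(dur), 1L)
  expect_equal(dur$duration_s, 30)

  # a track whose only event is incomplete contributes nothing
  ev2 <- run_detection(trace_track(c(0.6, 0.6, 0.85, 0.85)), 0.6)$events
  expect_equal(nrow(first_complete_event_durations(ev2)), 0L)

  # no events anywhere -> empty
  ev3 <- run_detection(trace_track(rep(0.6, 5)), 0.6)$events
  expect_equal(nrow(first_complete_event_durations(ev3)), 0L)
})

test_that("percent_elevated_timepoints counts per-timepoint threshold crossings", {
  det <- detection_params(background = 0.6)
  # 3 of 10 timepoints at/above B + 0.2 (>= comparison, so 0.80 counts)
  r <- c(0.6, 0.6, 0.80, 0.85, 0.9, 0.6, 0.6, 0.6, 0.6, 0.6)
  pe <- percent_elevated_timepoints(compute_ratio(trace_track(r)), det)
  expect_equal(unname(pe["selecting"]), 0.3)

  # bounds: all below -> 0; all at/above -> 1
  expect_equal(unname(percent_elevated_timepoints(
    compute_ratio(trace_track(rep(0.6, 8))), det)), 0)
  expect_equal(unname(percent_elevated_timepoints(
    compute_ratio(trace_track(rep(0.9, 8))), det)), 1)

  # invariant to track order and concatenation of runs
  a <- trace_track(r, track_id = "a", run_id = "A")
  b <- trace_track(rev(r), track_id = "b", run_id = "B")
  expect_equal(percent_elevated_timepoints(compute_ratio(stack_tracks(a, b)), det),
               percent_elevated_timepoints(compute_ratio(stack_tracks(b, a)), det))
  expect_equal(unname(percent_elevated_timepoints(
    compute_ratio(stack_tracks(a, b)), det)["selecting"]), 0.3)

  # per-condition split
  two <- stack_tracks(trace_track(r, track_id = "a"),
                      trace_track(rep(0.6, 10), track_id = "n",
                                  condition = "nonselecting"))
  pe2 <- percent_elevated_timepoints(compute_ratio(two), det)
  expect_equal(pe2, c(nonselecting = 0, selecting = 0.3))
})

test_that("event_frequency divides merged events by cumulative track time", {
  # no events -> 0 events/min over the compiled time
  quiet <- stack_tracks(trace_track(rep(0.6, 91), track_id = "q1"),
                        trace_track(rep(0.6, 91), track_id = "q2"),
                        trace_track(rep(0.6, 91), track_id = "q3"))
  fr <- run_detection(quiet, 0.6)
  expect_equal(event_frequency(fr$events, fr$det)$events_per_min, 0)
  expect_equal(event_frequency(fr$events, fr$det)$min_per_event, Inf)

  # 2 events over three 15-min tracks -> 2/45 per min (22.5 min/event)
  ev_trace <- c(rep(0.6, 10), 0.9, 0.9, 0.9, 0.65, 0.65, rep(0.6, 76))
  three <- stack_tracks(trace_track(ev_trace, track_id = "a"),
                        trace_track(ev_trace, track_id = "b"),
                        trace_track(rep(0.6, 91), track_id = "c"))
  fr <- run_detection(three, 0.6)
  res <- event_frequency(fr$events, fr$det)
  expect_equal(res$n_counted, 2L)
  expect_equal(res$cumulative_track_time_min, 45)
  expect_equal(res$events_per_min, 2 / 45)
  expect_equal(res$min_per_event, 22.5)

  # two bursts separated by 60 s of low signal: 2 hysteresis events but one
  # counted frequency event (< 4 min of quiescence merges them)
  r <- c(0.9, 0.9, 0.9, rep(0.65, 6), 0.9, 0.9, 0.9, 0.65, 0.65, rep(0.6, 20))
  fr <- run_detection(trace_track(r), 0.6)
  expect_equal(nrow(fr$events), 2L)
  expect_equal(fr$events$start_time_s[2] - fr$events$end_time_s[1], 60)
  expect_equal(event_frequency(fr$events, fr$det)$n_counted, 1L)

  # a gap of exactly the quiescence bound separates counted events
  r2 <- c(0.9, 0.9, 0.9, rep(0.65, 24), 0.9, 0.9, 0.9, 0.65, 0.65, rep(0.6, 5))
  fr2 <- run_detection(trace_track(r2), 0.6)
  expect_equal(fr2$events$start_time_s[2] - fr2$events$end_time_s[1], 240)
  expect_equal(event_frequency(fr2$events, fr2$det)$n_counted, 2L)

  # without boundary quiescence, truncated and edge events are not counted
  res_strict <- event_frequency(fr$events, fr$det, boundary_quiescence = FALSE)
  expect_equal(res_strict$n_counted, 0L)
})
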
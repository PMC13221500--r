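test_that("threshold crossing detection matches a linear scan", {
  tr <- bci_trace(seq(0, 10, by = 0.01), seq(0, 1, length.out = 1001),
                  region = "M1", units = "dff")
  hit <- detect_threshold_crossing(tr, 0.5, c(0, 10))
  scan <- tr$times[which(tr$values >= 0.5)[1]] # exhaustive scan oracle
  expect_equal(hit, scan)
  # never reached
  expect_true(is.na(detect_threshold_crossing(tr, 2, c(0, 10))))
  # constant at threshold from the window start -> first-sample rule
  tr2 <- bci_trace(seq(0, 1, by = 0.01), rep(0.5, 101), units = "dff")
  expect_equal(detect_threshold_crossing(tr2, 0.5, c(0.2, 1)), 0.2)
  expect_error(detect_threshold_crossing(tr, 0.5, c(20, 30)), "no samples")
})

test_that("a scripted GO trial follows the state-machine timing", {
  tr <- run_go_trial(perfect_agent(), quiet_profiles(), task_config(),
                     seed = 1, scripted_crossing = 5.0)
  expect_equal(tr$outcome, "success")
  expect_equal(tr$response_time, event_time(tr, "crossing"))
  expect_equal(event_time(tr, "crossing"), 5.0, tolerance = 0.03)
  expect_equal(event_time(tr, "go_cue"), 0)
  expect_equal(event_time(tr, "feedback"), event_time(tr, "crossing"))
  expect_equal(event_time(tr, "reward") - event_time(tr, "feedback"), 1.0)
  expect_equal(event_time(tr, "feedback_off") - event_time(tr, "feedback"), 0.5)
})

test_that("a GO miss fails at the end of the response window", {
  tr <- run_go_trial(perfect_agent(), quiet_profiles(), task_config(),
                     seed = 2, scripted_crossing = NA)
  expect_equal(tr$outcome, "failure")
  expect_true(is.na(tr$response_time))
  expect_true(is.na(event_time(tr, "feedback")))
  expect_true(is.na(event_time(tr, "reward")))
  expect_equal(event_time(tr, "failure"), 30)
  expect_equal(tr$conclude_s, 30)
})

test_that("withdrawal variants omit the event and its transient", {
  pr <- quiet_profiles()
  tr <- run_go_trial(perfect_agent(), pr, task_config(), seed = 3,
                     variant = "GO_no_reward", scripted_crossing = 5,
                     keep_components = TRUE)
  expect_equal(tr$outcome, "success")
  expect_false("reward" %in% tr$events$event_class)
  expect_true("feedback" %in% tr$events$event_class)
  expect_true(all(tr$components$M1[, "reward"] == 0))
  expect_true(any(tr$components$M1[, "feedback"] > 0))

  tr2 <- run_go_trial(perfect_agent(), pr, task_config(), seed = 3,
                      variant = "GO_no_feedback", scripted_crossing = 5,
                      keep_components = TRUE)
  expect_false("feedback" %in% tr2$events$event_class)
  expect_true("reward" %in% tr2$events$event_class)
  expect_true(all(tr2$components$M1[, "feedback"] == 0))

  tr3 <- run_go_trial(perfect_agent(), pr, task_config(), seed = 3,
                      variant = "GO_no_cue", scripted_crossing = 5,
                      keep_components = TRUE)
  expect_false("go_cue" %in% tr3$events$event_class)
  expect_true(all(tr3$components$M1[, "go_cue"] == 0))
})

test_that("NO-GO trials implement hold, failure and premature rules", {
  pr <- quiet_profiles()
  cfg <- task_config()
  # full inhibition: feedback at the hold end, reward 1 s later
  tr <- run_nogo_trial(perfect_agent(), pr, cfg, seed = 4,
                       scripted_crossing = NA)
  expect_equal(tr$outcome, "success")
  expect_equal(event_time(tr, "stop_cue"), 2.0)
  expect_equal(event_time(tr, "feedback"), 15.0)
  expect_equal(event_time(tr, "reward"), 16.0)
  expect_true(is.na(tr$response_time))
  # crossing during the hold
  tr2 <- run_nogo_trial(perfect_agent(), pr, cfg, seed = 5,
                        scripted_crossing = 7.0)
  expect_equal(tr2$outcome, "failure")
  expect_equal(tr2$response_time, 7.0, tolerance = 0.03)
  expect_false(any(c("feedback", "reward") %in% tr2$events$event_class))
  expect_false(tr2$premature)
  # crossing before the stop cue is premature
  tr3 <- run_nogo_trial(perfect_agent(), pr, cfg, seed = 6,
                        scripted_crossing = 1.0)
  expect_equal(tr3$outcome, "failure")
  expect_true(tr3$premature)
  expect_equal(tr3$response_time, 1.0, tolerance = 0.03)
})

test_that("event order and reward latency hold over stochastic trials", {
  ag <- agent_params()
  pr <- default_region_profiles()
  cfg <- task_config()
  for (s in 1:40) {
    tr <- if (s %% 2 == 0) {
      run_go_trial(ag, pr, cfg, seed = s, synthesize = s %% 4 == 0)
    } else {
      run_nogo_trial(ag, pr, cfg, seed = s, synthesize = (s + 1) %% 4 == 0)
    }
    ev <- tr$events
    expect_false(is.unsorted(ev$time_s))
    fb <- event_time(tr, "feedback")
    rw <- event_time(tr, "reward")
    cr <- event_time(tr, "crossing")
    if (!is.na(fb) && !is.na(rw)) expect_equal(rw - fb, cfg$reward_delay)
    if (!is.na(cr)) {
      expect_equal(tr$response_time, cr)
      expect_gte(cr, 0)
    }
    # closed-loop consistency: feedback exists iff a GO crossing or a
    # completed NO-GO hold
    if (tr$trial_type == "GO") {
      expect_equal(!is.na(fb), !is.na(cr))
    } else {
      expect_equal(!is.na(fb), is.na(cr))
    }
  }
})

test_that("scheduler composition follows p_go", {
  expect_true(all(schedule_trials(50, task_config(p_go = 1), seed = 1) == "GO"))
  expect_true(all(schedule_trials(50, task_config(p_go = 0), seed = 1) == "NOGO"))
  s <- schedule_trials(20000, task_config(), seed = 2)
  se <- sqrt(0.67 * 0.33 / 20000)
  expect_lt(abs(mean(s == "GO") - 0.67), 3 * se)
  # deck scheduler hits the count exactly
  d <- schedule_trials(100, task_config(scheduler = "deck"), seed = 3)
  expect_equal(sum(d == "GO"), 67)
})

test_that("sessions terminate at the success target", {
  log <- run_session(perfect_agent(), quiet_profiles(), fast_config(),
                     seed = 1, synthesize = FALSE)
  expect_equal(log$n_presented, 10) # no failures: presented == target
  expect_equal(log$n_success, 10)
  expect_false(log$capped)
  n_succ <- sum(vapply(log$trials, function(t) t$outcome == "success",
                       logical(1)))
  expect_equal(n_succ, log$config$n_success_target)
})

test_that("presented GO trials scale geometrically with success rate", {
  ag <- agent_params(p_go_success = 0.5, p_inhibit = 1, premature_rate = 0)
  cfg <- task_config(n_success_target = 30, max_trials = 300)
  pres <- succ <- 0
  for (s in 1:8) {
    log <- run_session(ag, quiet_profiles(), cfg, seed = s, synthesize = FALSE)
    go <- vapply(log$trials, function(t) t$trial_type == "GO", logical(1))
    pres <- pres + sum(go)
    succ <- succ + sum(vapply(log$trials[go], function(t) t$outcome == "success",
                              logical(1)))
  }
  expect_equal(pres / succ, 2, tolerance = 0.2)
})

test_that("identical session seeds reproduce the session exactly", {
  ag <- agent_params()
  l1 <- run_session(ag, default_region_profiles(), fast_config(), seed = 9,
                    synthesize = TRUE, regions = "M1")
  l2 <- run_session(ag, default_region_profiles(), fast_config(), seed = 9,
                    synthesize = TRUE, regions = "M1")
  expect_identical(session_events(l1), session_events(l2))
  expect_identical(l1$trials[[1]]$traces$M1$values,
                   l2$trials[[1]]$traces$M1$values)
  expect_identical(l1$licks, l2$licks)
})

test_that("chemogenetic experiments tag exactly three CNO-on days per mouse", {
  ex <- run_experiment("chemogenetic", config = fast_config(), seed = 2,
                       n_mice = c(control = 2, hM4D = 2, hM3D = 2))
  m <- ex$meta
  expect_equal(nrow(m), 6 * 6)
  per_mouse <- tapply(m$cno_on, m$mouse_id, sum)
  expect_true(all(per_mouse == 3))
  # manipulation active only on CNO days in the DREADD groups
  expect_true(all(m$mode[m$group == "hM3D" & m$cno_on] == "hM3D"))
  expect_true(all(m$mode[m$group == "hM3D" & !m$cno_on] == "control"))
  expect_true(all(m$mode[m$group == "control"] == "control"))
})

test_that("skipping excluded days leaves included sessions identical", {
  n <- c(control = 2, hM4D = 2, hM3D = 2)
  full <- run_experiment("chemogenetic", config = fast_config(), seed = 5,
                         n_mice = n)
  lean <- run_experiment("chemogenetic", config = fast_config(), seed = 5,
                         n_mice = n, included_only = TRUE)
  inc <- included_sessions(full)
  key <- function(m) paste(m$mouse_id, m$day)
  match_idx <- match(key(full$meta[full$meta$session %in% inc, ]),
                     key(lean$meta))
  expect_false(any(is.na(match_idx)))
  for (j in seq_along(inc)) {
    expect_identical(
      session_events(full$sessions[[inc[j]]]),
      session_events(lean$sessions[[lean$meta$session[match_idx[j]]]])
    )
  }
})

test_that("optogenetic designs use published group sizes and per-trial modes", {
  ex <- run_experiment("optogenetic_feedback", config = fast_config(),
                       seed = 3, days = 1)
  m <- ex$meta
  expect_equal(sum(m$group == "control"), 6)
  expect_equal(sum(m$group == "eNpHR"), 7)
  expect_true(all(m$mode[m$group == "eNpHR"] == "eNpHR_at_feedback"))
})

test_that("the random-reward design runs a single decoupled-reward group", {
  ex <- run_experiment("random_reward", config = fast_config(
    n_success_target = 3, max_trials = 10
  ), seed = 14, n_mice = c(random_reward = 2))
  expect_equal(nrow(ex$meta), 2)
  types <- unlist(lapply(ex$sessions, function(l) {
    vapply(l$trials, function(t) t$trial_type, character(1))
  }))
  expect_true(all(types == "random_reward"))
})

test_that("random-reward trials deliver cue-coupled rewards without feedback", {
  log <- run_session(agent_params(), quiet_profiles(),
                     fast_config(n_success_target = 5), seed = 8,
                     synthesize = FALSE, trial_variant = "random_reward")
  expect_equal(log$n_success, 5)
  for (tr in log$trials) {
    expect_equal(tr$trial_type, "random_reward")
    expect_equal(event_time(tr, "go_cue"), event_time(tr, "reward"))
    expect_false("feedback" %in% tr$events$event_class)
    expect_false("crossing" %in% tr$events$event_class)
  }
})
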
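test_that("moving average preserves constants and stays within input range", {
  tr <- bci_trace(seq(0, 2, by = 0.01), rep(3.5, 201))
  sm <- moving_average(tr)
  expect_true(all(sm$values == 3.5))
  expect_equal(sm$rate, 100)
  set.seed(1)
  tr2 <- bci_trace(seq(0, 2, by = 0.01), rnorm(201))
  sm2 <- moving_average(tr2, span_ms = 50, step_ms = 10)
  expect_lte(max(sm2$values), max(tr2$values))
  expect_gte(min(sm2$values), min(tr2$values))
})

test_that("moving average equals the exhaustive window-mean oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    rate <- sample(c(50, 100, 200), 1)
    span <- sample(c(20, 40, 60), 1)
    step <- sample(c(10, 20), 1)
    if (span / 1000 < 1 / rate) next
    tr <- bci_trace(seq(0, by = 1 / rate, length.out = n), rnorm(n))
    sm <- moving_average(tr, span_ms = span, step_ms = step)
    or <- oracle_moving_average(tr$times, tr$values, span, step)
    expect_equal(sm$times, or$times, tolerance = 1e-9)
    expect_equal(sm$values, or$values, tolerance = 1e-12)
  }
})

test_that("span == step gives non-overlapping block means", {
  v <- c(0, 3, 6, 9)
  tr <- bci_trace(seq(0, 0.03, by = 0.01), v)
  sm <- moving_average(tr, span_ms = 10, step_ms = 10)
  # centered 10-ms windows on a 10-ms grid: each window holds one sample
  expect_equal(sm$values, v)
  tr2 <- bci_trace(seq(0, 0.07, by = 0.01), 1:8)
  sm2 <- moving_average(tr2, span_ms = 20, step_ms = 20)
  or <- oracle_moving_average(tr2$times, tr2$values, 20, 20)
  expect_equal(sm2$values, or$values)
})

test_that("smoothing rejects spans shorter than a sample period", {
  tr <- bci_trace(seq(0, 1, by = 0.1), rnorm(11))
  expect_error(moving_average(tr, span_ms = 20, step_ms = 10), "shorter")
})

test_that("dF/F conversion follows (F - F0)/F0 with a cue-locked baseline", {
  tr <- bci_trace(seq(0, 1, by = 0.01), rep(2, 101))
  dff <- compute_dff(tr, cue_time = 0.2)
  expect_true(all(dff$values == 0))
  expect_equal(dff$units, "dff")
  # known F0 and a later excursion
  v <- rep(1, 101)
  v[81] <- 1.5
  dff2 <- compute_dff(bci_trace(seq(0, 1, by = 0.01), v), cue_time = 0.1)
  expect_equal(dff2$values[81], 0.5)
})

test_that("the F0 window mean matches the closed form on a ramp", {
  # F = 2 + 3 t sampled at 1 kHz; F0 over [t0, t0 + 10 ms] = 2 + 3 (t0 + 0.005)
  t <- seq(0, 1, by = 0.001)
  tr <- bci_trace(t, 2 + 3 * t)
  t0 <- 0.25
  f0 <- 2 + 3 * (t0 + 0.005)
  dff <- compute_dff(tr, cue_time = t0)
  expect_equal(dff$values, (tr$values - f0) / f0, tolerance = 1e-12)
})

test_that("dF/F is invariant under positive rescaling of F", {
  set.seed(3)
  v <- 2 + abs(rnorm(201))
  t <- seq(0, 2, by = 0.01)
  d1 <- compute_dff(bci_trace(t, v), cue_time = 0.5)
  d2 <- compute_dff(bci_trace(t, 7.3 * v), cue_time = 0.5)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("non-positive baselines are rejected", {
  t <- seq(0, 1, by = 0.01)
  expect_error(compute_dff(bci_trace(t, rep(-1, 101)), cue_time = 0.2),
               "degenerate baseline")
})

test_that("event alignment windows and truncation flags are correct", {
  t <- seq(0, 60, by = 0.01)
  v <- numeric(length(t))
  v[t == 30] <- 1 # delta-like transient
  tr <- bci_trace(t, v, units = "au")
  seg <- align_to_event(tr, 30, pre = 15, post = 10)
  expect_false(seg$truncated)
  expect_equal(range(seg$times), c(-15, 10))
  expect_equal(seg$times[which.max(seg$values)], 0)
  seg2 <- align_to_event(tr, 5, pre = 15, post = 10)
  expect_true(seg2$truncated)
  expect_equal(min(seg2$times), -5)
  seg3 <- align_to_event(tr, 30, pre = 10, post = 10)
  expect_equal(range(seg3$times), c(-10, 10))
  expect_error(align_to_event(tr, 100, 15, 10), "outside")
})

test_that("component peaks equal a brute-force window max", {
  pr <- quiet_profiles()$M1
  ev <- data.frame(event_class = c("go_cue", "crossing", "feedback", "reward"),
                   time_s = c(0, 5, 5, 6))
  gen <- ev[ev$event_class %in% c("go_cue", "feedback", "reward"), ]
  s <- synthesize_trial_trace(pr, gen, duration = 15, rate = 100, t_start = -2)
  dff <- compute_dff(s$trace, cue_time = 0)
  seg <- align_to_event(dff, 6, pre = 8, post = 9)
  pk <- extract_component_peaks(seg, ev)
  w <- default_component_windows()
  for (comp in c("go_cue", "feedback", "reward")) {
    anchor <- ev$time_s[ev$event_class == comp]
    lo <- anchor + w[[comp]][1] - 6
    hi <- anchor + w[[comp]][2] - 6
    brute <- max(seg$values[seg$times >= lo - 1e-9 & seg$times <= hi + 1e-9])
    expect_equal(pk$peak_dff[pk$component == comp], brute)
  }
  # stop cue absent on GO trials -> NA peak
  expect_true(is.na(pk$peak_dff[pk$component == "stop_cue"]))
})

test_that("an isolated reward transient yields a reward peak only", {
  pr <- quiet_profiles()$M1
  for (cls in c("go_cue", "stop_cue", "feedback", "volitional_ramp")) {
    pr$kernels[[cls]] <- transient_kernel(0, 0.05, 0.4)
  }
  a <- pr$kernels$reward$amplitude
  ev <- data.frame(event_class = c("go_cue", "crossing", "feedback", "reward"),
                   time_s = c(0, 5, 5, 6))
  s <- synthesize_trial_trace(pr, ev[ev$event_class == "reward", ],
                              duration = 15, rate = 100, t_start = -2)
  dff <- compute_dff(s$trace, cue_time = 0)
  seg <- align_to_event(dff, 6, pre = 8, post = 9)
  pk <- extract_component_peaks(seg, ev)
  expect_equal(pk$peak_dff[pk$component == "reward"], a, tolerance = 0.01)
  for (comp in c("go_cue", "feedback", "volitional")) {
    expect_equal(pk$peak_dff[pk$component == comp], 0, tolerance = 1e-9)
  }
})

test_that("all-zero segments give zero peaks", {
  tr <- bci_trace(seq(-5, 10, by = 0.01), numeric(1501), units = "dff")
  seg <- align_to_event(tr, 2, pre = 5, post = 5)
  ev <- data.frame(event_class = c("go_cue", "crossing", "feedback", "reward"),
                   time_s = c(-2, 2, 2, 3))
  pk <- extract_component_peaks(seg, ev)
  expect_true(all(pk$peak_dff[!is.na(pk$peak_dff)] == 0))
})

test_that("measured peaks track the noiseless composite within calibration error", {
  # identifiability under default amplitudes and noise: the windowed peak
  # measured after smoothing + dF/F matches the noiseless composite
  # windowed max within 10% for >= 95% of trials
  ag <- perfect_agent()
  cfg <- task_config()
  ok <- 0
  total <- 0
  for (s in 1:30) {
    tr_noisy <- run_go_trial(ag, default_region_profiles(), cfg, seed = s,
                             scripted_crossing = 4 + (s %% 3),
                             keep_components = TRUE)
    tr_clean <- run_go_trial(ag, quiet_profiles(), cfg, seed = s,
                             scripted_crossing = 4 + (s %% 3),
                             keep_components = TRUE)
    peaks <- function(tr, smooth) {
      raw <- tr$traces$M1
      if (smooth) raw <- moving_average(raw)
      dff <- compute_dff(raw, cue_time = 0)
      rw <- event_time(tr, "reward")
      seg <- align_to_event(dff, rw, pre = rw - dff$times[1],
                            post = max(dff$times) - rw)
      extract_component_peaks(seg, tr$events)
    }
    pn <- peaks(tr_noisy, smooth = TRUE)
    pc <- peaks(tr_clean, smooth = FALSE)
    for (comp in c("go_cue", "feedback", "reward", "volitional")) {
      truth <- pc$peak_dff[pc$component == comp]
      meas <- pn$peak_dff[pn$component == comp]
      total <- total + 1
      if (abs(meas - truth) <= 0.1 * max(truth, 0.1)) ok <- ok + 1
    }
  }
  expect_gte(ok / total, 0.95)
})
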
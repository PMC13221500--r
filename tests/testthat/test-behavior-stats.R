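test_that("success rates are successes over presented trials per type", {
  log <- run_session(perfect_agent(), quiet_profiles(), fast_config(),
                     seed = 1, synthesize = FALSE)
  expect_equal(success_rate(log, "GO"), 1)
  expect_equal(success_rate(log, "NOGO"), 1)
  # binomial convergence at p = 0.7
  ag <- agent_params(p_go_success = 0.7)
  cfg <- task_config(p_go = 1, n_success_target = 140, max_trials = 200)
  log2 <- run_session(ag, quiet_profiles(), cfg, seed = 2, synthesize = FALSE)
  n_go <- sum(vapply(log2$trials, function(t) t$trial_type == "GO", logical(1)))
  se <- sqrt(0.7 * 0.3 / n_go)
  expect_lt(abs(success_rate(log2, "GO") - 0.7), 3 * se)
  # a GO-only session has no NO-GO trials to rate
  expect_error(success_rate(log2, "NOGO"), "no presented trials")
})

test_that("response times are bookkept from the logged crossings", {
  ag <- agent_params()
  log <- run_session(ag, default_region_profiles(), fast_config(), seed = 3,
                     synthesize = FALSE)
  rts <- response_times(log, "GO")
  crossings <- unlist(lapply(log$trials, function(tr) {
    if (tr$trial_type == "GO" && tr$outcome == "success") {
      tr$events$time_s[tr$events$event_class == "crossing"]
    }
  }))
  expect_identical(rts, crossings)
  # successful NO-GO trials have no crossing, hence no response time
  log2 <- run_session(perfect_agent(), quiet_profiles(),
                      fast_config(p_go = 0), seed = 4, synthesize = FALSE)
  expect_length(response_times(log2, "NOGO"), 0)
})

test_that("the training criterion needs three consecutive days at 85%", {
  expect_true(training_criterion(c(0.9, 0.9, 0.9)))
  expect_true(training_criterion(c(0.9, 0.8, 0.9, 0.9, 0.9)))
  expect_false(training_criterion(c(0.84, 0.84, 0.84)))
  expect_false(training_criterion(c(0.9, 0.9, 0.8, 0.9, 0.84)))
  expect_true(training_criterion(c(0.85, 0.85, 0.85)))
  expect_error(training_criterion(c(0.9, 0.9)), "at least 3")
  expect_error(training_criterion(c(0.9, 0.9, 1.2)), "\\[0, 1\\]")
})

test_that("the pooled t test matches the closed form", {
  o <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  r <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
  expect_equal(r$df, 4)
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(sample(3:9, 1))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    o <- oracle_pooled_t(a, b)
    r <- unpaired_t_test(a, b)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
    rs <- unpaired_t_test(b, a)
    expect_equal(rs$statistic, -r$statistic, tolerance = 1e-12)
    expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate t-test inputs are handled explicitly", {
  r <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)
  r2 <- unpaired_t_test(c(2, 2), c(3, 3))
  expect_true(r2$degenerate)
  expect_error(unpaired_t_test(1, c(2, 3)), "at least 2")
})

test_that("Mann-Whitney U matches full enumeration for small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1) # 2/20 arrangements as extreme
  expect_true(r$exact)
  set.seed(6)
  for (na in 2:6) {
    for (nb in 2:6) {
      a <- rnorm(na)
      b <- rnorm(nb, mean = 0.5)
      o <- oracle_mw_exact(a, b)
      r <- mann_whitney_u(a, b)
      expect_equal(r$U, o$U)
      expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
      rs <- mann_whitney_u(b, a)
      expect_equal(rs$U, r$U)
      expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
    }
  }
  # equal samples up to permutation
  expect_equal(mann_whitney_u(c(3, 1, 2), c(2, 3, 1))$p_value, 1)
})

test_that("significance stars follow the reporting convention", {
  expect_equal(significance_stars(0.2), "")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(0.0009), "***")
})

test_that("per-mouse averaging yields one point per mouse", {
  ex <- run_experiment("chemogenetic", config = fast_config(), seed = 7,
                       n_mice = c(control = 3, hM4D = 2, hM3D = 2),
                       included_only = TRUE)
  ms <- mouse_summary(ex, "go_success")
  expect_equal(nrow(ms), 7)
  expect_equal(anyDuplicated(ms$mouse_id), 0)
  expect_equal(sum(ms$group == "control"), 3)
  # the summary averages the three CNO-on sessions
  m1 <- ms$value[ms$mouse_id == "control_01"]
  inc <- included_sessions(ex)
  vals <- vapply(inc, function(i) {
    log <- ex$sessions[[i]]
    if (log$mouse_id == "control_01") success_rate(log, "GO") else NA_real_
  }, numeric(1))
  expect_equal(m1, mean(vals, na.rm = TRUE))
})

test_that("group comparisons report test, p-value and stars", {
  ex <- run_experiment("optogenetic_feedback", config = fast_config(
    n_success_target = 20, max_trials = 100
  ), seed = 8, days = 1)
  cmp <- summarize_and_compare(ex, "go_success", test = "mann_whitney_u")
  expect_equal(cmp$group, "eNpHR")
  expect_equal(cmp$n_control, 6)
  expect_equal(cmp$n_group, 7)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_equal(cmp$stars, significance_stars(cmp$p_value))
  cmp2 <- summarize_and_compare(ex, "go_rt", test = "both")
  expect_false(is.na(cmp2$p_t))
  expect_false(is.na(cmp2$p_u))
  expect_error(
    summarize_and_compare(
      run_experiment("optogenetic_cue", config = fast_config(), seed = 9,
                     days = 1, n_mice = c(control = 1, eNpHR = 2)),
      "go_success"
    ),
    "fewer than 2 mice"
  )
})

test_that("seed-matched identical groups are statistically indistinguishable", {
  cfg <- fast_config(n_success_target = 15, max_trials = 80)
  logs_a <- lapply(1:4, function(i) run_session(agent_params(),
                                                quiet_profiles(), cfg,
                                                seed = 50 + i,
                                                synthesize = FALSE))
  logs_b <- lapply(1:4, function(i) run_session(agent_params(),
                                                quiet_profiles(), cfg,
                                                seed = 50 + i,
                                                synthesize = FALSE))
  a <- vapply(logs_a, success_rate, numeric(1), trial_type = "GO")
  b <- vapply(logs_b, success_rate, numeric(1), trial_type = "GO")
  expect_identical(a, b)
  expect_equal(mann_whitney_u(a, b)$p_value, 1)
})
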
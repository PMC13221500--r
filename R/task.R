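#' Detect the first threshold crossing of a signal
#'
#' Scans a dF/F trace inside a time window and returns the time of the
#' first sample at which the signal reaches the threshold: either an
#' upward crossing (previous sample below, current at or above) or the
#' first sample of the window if the signal already starts at or above the
#' threshold. This is the closed-loop trigger of the paradigm: decisions
#' are made on the simulation grid, so a one-sample trigger latency is
#' inherent.
#'
#' @param trace a [bci_trace()] (typically dF/F)
#' @param threshold threshold in the trace's units
#' @param window numeric length-2 vector `c(t0, t1)` within the trace
#' @return crossing time in seconds, or `NA_real_` if never reached
#' @export
detect_threshold_crossing <- function(trace, threshold, window) {
  stopifnot(inherits(trace, "bci_trace"), length(window) == 2)
  idx <- which(trace$times >= window[1] & trace$times <= window[2])
  if (length(idx) == 0) {
    stop("`window` contains no samples of the trace", call. = FALSE)
  }
  v <- trace$values[idx]
  above <- v >= threshold
  if (!any(above)) {
    return(NA_real_)
  }
  first <- which(above)[1]
  if (first == 1) {
    return(trace$times[idx[1]])
  }
  # first sample at/above with previous below; since `first` is the first
  # above-threshold sample, its predecessor is below by construction
  trace$times[idx[first]]
}

#' Round a time onto the simulation grid
#' @keywords internal
grid_round <- function(t, rate) {
  round(t * rate) / rate
}

#' Resolve the control threshold (dF/F units)
#'
#' @param config a [task_config()]
#' @param profile the controlled region's [region_profile()]
#' @param dff_pre pre-cue baseline dF/F samples (adaptive rule), or `NULL`
#'   for the analytic baseline statistics implied by the generator
#' @keywords internal
resolve_threshold <- function(config, profile, dff_pre = NULL) {
  rule <- config$threshold_rule
  if (rule$type == "fixed") {
    return(rule$value)
  }
  if (!is.null(dff_pre) && length(dff_pre) >= 2) {
    return(mean(dff_pre) + rule$k * stats::sd(dff_pre))
  }
  rule$k * profile$noise_sd / profile$baseline_F
}

#' Schedule trial types
#'
#' Draws the GO/NO-GO sequence for a session. The default scheduler draws
#' each trial type independently with `P(GO) = p_go`; the `"deck"`
#' scheduler shuffles a fixed-count deck with `round(p_go * n)` GO trials.
#'
#' @param n number of trial types to draw
#' @param config a [task_config()]
#' @param seed integer seed or `NULL`
#' @return character vector of `"GO"` / `"NOGO"`
#' @export
schedule_trials <- function(n, config = task_config(), seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) {
    return(character(0))
  }
  with_seed(seed, {
    if (config$scheduler == "bernoulli") {
      ifelse(stats::runif(n) < config$p_go, "GO", "NOGO")
    } else {
      n_go <- round(config$p_go * n)
      sample(c(rep("GO", n_go), rep("NOGO", n - n_go)))
    }
  })
}

#' Construct a trial result record
#' @keywords internal
trial_result <- function(trial_index, trial_type, outcome, events,
                         response_time, threshold_used, conclude_s,
                         premature = FALSE, traces = NULL, components = NULL,
                         seed = NULL) {
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(
      trial_index = trial_index,
      trial_type = trial_type,
      outcome = outcome,
      events = events,
      response_time = response_time,
      threshold_used = threshold_used,
      conclude_s = conclude_s,
      premature = premature,
      traces = traces,
      components = components,
      seed = seed
    ),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> #%d %s: %s", x$trial_index, x$trial_type, x$outcome))
  if (!is.na(x$response_time)) cat(sprintf(", RT %.2f s", x$response_time))
  cat("\n")
  ev <- paste(sprintf("%s@%.2f", x$events$event_class, x$events$time_s),
              collapse = ", ")
  cat("  events: ", ev, "\n")
  invisible(x)
}

#' Time of a named event within a trial (NA if absent)
#' @param trial a `trial_result`
#' @param event_class event class name
#' @export
event_time <- function(trial, event_class) {
  t <- trial$events$time_s[trial$events$event_class == event_class]
  if (length(t) == 0) NA_real_ else t[1]
}

# Synthesise the requested regions for a trial given its final event list.
synth_regions <- function(profiles, regions, gen_events, mode, config,
                          t_end, seed, keep_components = FALSE) {
  traces <- list()
  components <- list()
  for (i in seq_along(regions)) {
    rg <- regions[i]
    prof <- profiles[[rg]]
    if (is.null(prof)) {
      stop("no region profile supplied for region ", rg, call. = FALSE)
    }
    s <- synthesize_trial_trace(
      prof, gen_events, mode = mode,
      duration = config$pre_baseline_s + t_end,
      rate = config$rate,
      seed = derive_seed(seed, 100 + i),
      t_start = -config$pre_baseline_s
    )
    traces[[rg]] <- s$trace
    if (keep_components) components[[rg]] <- s$components
  }
  list(traces = traces, components = if (keep_components) components else NULL)
}

# Memoised crossing offsets: the grid search depends only on the kernel,
# the raw-level threshold and the rate, which are constant within (and
# usually across) sessions.
.offset_cache <- new.env(parent = emptyenv())

cached_crossing_offset <- function(kernel, level, rate) {
  key <- sprintf("%.12g|%.12g|%.12g|%.12g|%.12g",
                 kernel$amplitude, kernel$rise_tau, kernel$decay_tau,
                 level, rate)
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  val <- kernel_crossing_offset(kernel, level, rate)
  .offset_cache[[key]] <- val
  val
}

# Shared machinery: place the volitional ramp so that the noiseless
# closed-loop crossing lands on `tc` (grid-rounded).
place_ramp <- function(profiles, config, threshold, tc) {
  vk <- profiles$M1$kernels$volitional_ramp
  level <- threshold * profiles$M1$baseline_F
  delta <- cached_crossing_offset(vk, level, config$rate)
  if (is.na(delta)) {
    return(NULL) # volitional transient cannot reach threshold
  }
  tc <- grid_round(tc, config$rate)
  list(event_time = tc - delta, crossing = tc)
}

#' Run one GO-family trial
#'
#' Executes the closed-loop GO trial state machine: GO cue at `t = 0`
#' (omitted in the `GO_no_cue` withdrawal variant), monitoring of the
#' agent-generated M1 dF/F signal for a threshold crossing within the GO
#' window, feedback at the crossing (omitted in `GO_no_feedback`), and
#' reward `reward_delay` seconds after feedback onset (omitted in
#' `GO_no_reward`). Withdrawn events are also withheld from the trace
#' generator, so the corresponding calcium transients vanish. Failure is
#' declared at the end of the GO window.
#'
#' With `synthesize = TRUE` the trial is resolved against a synthesised
#' noisy trace (two-pass generation with a shared noise stream, so the
#' post-crossing feedback/reward transients do not perturb the detected
#' crossing); with `synthesize = FALSE` the crossing is the noiseless
#' closed-loop solution on the same grid (fast path for behavioral
#' endpoints).
#'
#' @param agent an [agent_params()] (unmanipulated; the mode is applied
#'   internally)
#' @param profiles named list of [region_profile()]s (must include `M1`)
#' @param config a [task_config()]
#' @param mode a [manipulation_mode()] or mode name
#' @param variant one of `GO`, `GO_no_cue`, `GO_no_feedback`, `GO_no_reward`
#' @param seed integer seed
#' @param synthesize synthesise traces (`TRUE`) or behavior-only fast path
#' @param regions regions to synthesise traces for
#' @param scripted_crossing `NULL` for stochastic behavior; a time in
#'   seconds to force the intended crossing; `NA` to force a miss
#' @param trial_index index recorded in the result
#' @param keep_components keep per-class generator components (tests)
#' @param .preapplied internal: the caller already ran
#'   [apply_manipulation()] on `agent` and `profiles`
#' @return a `trial_result`
#' @export
run_go_trial <- function(agent, profiles, config = task_config(),
                         mode = "control", variant = "GO", seed = 1,
                         synthesize = TRUE, regions = "M1",
                         scripted_crossing = NULL, trial_index = 1L,
                         keep_components = FALSE, .preapplied = FALSE) {
  stopifnot(variant %in% GO_VARIANTS)
  mode <- as_manipulation_mode(mode)
  if (!.preapplied) {
    mm <- apply_manipulation(agent, profiles, mode)
    agent <- mm$agent
    profiles <- mm$profiles
  }
  rate <- config$rate

  # intended behavior (all draws taken unconditionally so that streams are
  # aligned across manipulation strengths under a common seed)
  if (is.null(scripted_crossing)) {
    draws <- with_seed(seed, list(u = stats::runif(1), z = stats::rnorm(1)))
    success_intent <- draws$u < agent$p_go_success
    lat <- agent$go_latency_mean + agent$go_latency_sd * draws$z
    lat <- min(max(lat, 0.2), config$go_window - agent$ramp_duration - 0.5)
    tc_intend <- lat + agent$ramp_duration
  } else {
    success_intent <- !is.na(scripted_crossing)
    tc_intend <- if (success_intent) scripted_crossing else NA_real_
  }

  thr <- resolve_threshold(config, profiles$M1)
  ramp <- if (success_intent) place_ramp(profiles, config, thr, tc_intend) else NULL
  ev_cls <- character(0)
  ev_t <- numeric(0)
  if (variant != "GO_no_cue") {
    ev_cls <- "go_cue"
    ev_t <- 0
  }
  if (synthesize) {
    gen_events <- data.frame(
      event_class = c(ev_cls, if (!is.null(ramp)) "volitional_ramp"),
      time_s = c(ev_t, if (!is.null(ramp)) ramp$event_time),
      stringsAsFactors = FALSE
    )
    dur1 <- config$go_window + config$reward_delay + config$post_s
    s1 <- synthesize_trial_trace(
      profiles$M1, gen_events, mode = mode,
      duration = config$pre_baseline_s + dur1, rate = rate,
      seed = derive_seed(seed, 101), t_start = -config$pre_baseline_s
    )
    dff <- compute_dff(s1$trace, cue_time = 0)
    if (config$threshold_rule$type == "adaptive") {
      thr <- resolve_threshold(config, profiles$M1,
                               dff$values[dff$times < 0])
    }
    crossing <- detect_threshold_crossing(dff, thr, c(0, config$go_window))
  } else {
    crossing <- if (!is.null(ramp)) ramp$crossing else NA_real_
    if (!is.na(crossing) && crossing > config$go_window) crossing <- NA_real_
  }

  if (!is.na(crossing)) {
    outcome <- "success"
    ev_cls <- c(ev_cls, "crossing")
    ev_t <- c(ev_t, crossing)
    if (variant != "GO_no_feedback") {
      ev_cls <- c(ev_cls, "feedback", "feedback_off")
      ev_t <- c(ev_t, crossing, crossing + config$feedback_duration)
    }
    if (variant != "GO_no_reward") {
      ev_cls <- c(ev_cls, "reward")
      ev_t <- c(ev_t, crossing + config$reward_delay)
    }
    conclude <- crossing + config$reward_delay
    response_time <- crossing
  } else {
    outcome <- "failure"
    ev_cls <- c(ev_cls, "failure")
    ev_t <- c(ev_t, config$go_window)
    conclude <- config$go_window
    response_time <- NA_real_
  }
  ev_cls <- c(ev_cls, "iti_start")
  ev_t <- c(ev_t, conclude)
  events <- quick_df(event_class = ev_cls, time_s = ev_t)

  traces <- NULL
  components <- NULL
  if (synthesize) {
    gen_final <- events[events$event_class %in% KERNEL_EVENT_CLASSES, , drop = FALSE]
    if (!is.null(ramp)) {
      gen_final <- rbind(gen_final, data.frame(event_class = "volitional_ramp",
                                               time_s = ramp$event_time))
    }
    sy <- synth_regions(profiles, regions, gen_final, mode, config,
                        t_end = conclude + config$post_s, seed = seed,
                        keep_components = keep_components)
    traces <- sy$traces
    components <- sy$components
  }

  trial_result(trial_index, variant, outcome, events, response_time,
               thr, conclude, traces = traces, components = components,
               seed = seed)
}

#' Run one NO-GO trial
#'
#' GO cue at `t = 0`, stop cue `stop_delay` seconds later; the agent must
#' keep the M1 signal below threshold until `stop_delay + hold_duration`.
#' A completed hold triggers feedback at the hold end and reward
#' `reward_delay` later. Any crossing inside `[0, stop_delay +
#' hold_duration]` is a failure with a response time measured from trial
#' onset; crossings before the stop cue are flagged premature and scored
#' as failures.
#'
#' @inheritParams run_go_trial
#' @param scripted_crossing `NULL` for stochastic behavior; a time to force
#'   a crossing; `NA` to force full inhibition
#' @return a `trial_result`
#' @export
run_nogo_trial <- function(agent, profiles, config = task_config(),
                           mode = "control", seed = 1,
                           synthesize = TRUE, regions = "M1",
                           scripted_crossing = NULL, trial_index = 1L,
                           keep_components = FALSE, .preapplied = FALSE) {
  mode <- as_manipulation_mode(mode)
  if (!.preapplied) {
    mm <- apply_manipulation(agent, profiles, mode)
    agent <- mm$agent
    profiles <- mm$profiles
  }
  rate <- config$rate
  hold_end <- config$stop_delay + config$hold_duration

  if (is.null(scripted_crossing)) {
    draws <- with_seed(seed, stats::runif(3))
    if (draws[1] < agent$premature_rate) {
      tc_intend <- 0.5 + draws[3] * (config$stop_delay - 0.55)
    } else if (draws[2] < agent$p_inhibit) {
      tc_intend <- NA_real_
    } else {
      lo <- config$stop_delay + 0.3
      hi <- hold_end - 0.5
      tc_intend <- lo + draws[3] * (hi - lo)
    }
  } else {
    tc_intend <- scripted_crossing
  }

  thr <- resolve_threshold(config, profiles$M1)
  ramp <- if (!is.na(tc_intend)) place_ramp(profiles, config, thr, tc_intend) else NULL
  ev_cls <- c("go_cue", "stop_cue")
  ev_t <- c(0, config$stop_delay)
  if (synthesize) {
    gen_events <- data.frame(
      event_class = c(ev_cls, if (!is.null(ramp)) "volitional_ramp"),
      time_s = c(ev_t, if (!is.null(ramp)) ramp$event_time),
      stringsAsFactors = FALSE
    )
    dur1 <- hold_end + config$reward_delay + config$post_s
    s1 <- synthesize_trial_trace(
      profiles$M1, gen_events, mode = mode,
      duration = config$pre_baseline_s + dur1, rate = rate,
      seed = derive_seed(seed, 101), t_start = -config$pre_baseline_s
    )
    dff <- compute_dff(s1$trace, cue_time = 0)
    if (config$threshold_rule$type == "adaptive") {
      thr <- resolve_threshold(config, profiles$M1, dff$values[dff$times < 0])
    }
    crossing <- detect_threshold_crossing(dff, thr, c(0, hold_end))
  } else {
    crossing <- if (!is.null(ramp)) ramp$crossing else NA_real_
    if (!is.na(crossing) && crossing > hold_end) crossing <- NA_real_
  }

  premature <- FALSE
  if (is.na(crossing)) {
    outcome <- "success"
    ev_cls <- c(ev_cls, "feedback", "feedback_off", "reward")
    ev_t <- c(ev_t, hold_end, hold_end + config$feedback_duration,
              hold_end + config$reward_delay)
    conclude <- hold_end + config$reward_delay
    response_time <- NA_real_
  } else {
    outcome <- "failure"
    premature <- crossing < config$stop_delay
    ev_cls <- c(ev_cls, "crossing", "failure")
    ev_t <- c(ev_t, crossing, crossing)
    conclude <- crossing
    response_time <- crossing
  }
  ev_cls <- c(ev_cls, "iti_start")
  ev_t <- c(ev_t, conclude)
  events <- quick_df(event_class = ev_cls, time_s = ev_t)

  traces <- NULL
  components <- NULL
  if (synthesize) {
    gen_final <- events[events$event_class %in% KERNEL_EVENT_CLASSES, , drop = FALSE]
    if (!is.null(ramp)) {
      gen_final <- rbind(gen_final, data.frame(event_class = "volitional_ramp",
                                               time_s = ramp$event_time))
    }
    sy <- synth_regions(profiles, regions, gen_final, mode, config,
                        t_end = conclude + config$post_s, seed = seed,
                        keep_components = keep_components)
    traces <- sy$traces
    components <- sy$components
  }

  trial_result(trial_index, "NOGO", outcome, events, response_time, thr,
               conclude, premature = premature, traces = traces,
               components = components, seed = seed)
}

#' Run one random-reward trial
#'
#' The goal-direction control: the GO cue is co-played with a reward
#' delivered at a random (exponentially distributed) latency, decoupled
#' from the calcium signal; no feedback tone and no threshold monitoring.
#'
#' @inheritParams run_go_trial
#' @return a `trial_result`
#' @export
run_random_reward_trial <- function(agent, profiles, config = task_config(),
                                    mode = "control", seed = 1,
                                    synthesize = TRUE, regions = "M1",
                                    trial_index = 1L, keep_components = FALSE,
                                    .preapplied = FALSE) {
  mode <- as_manipulation_mode(mode)
  if (!.preapplied) {
    mm <- apply_manipulation(agent, profiles, mode)
    profiles <- mm$profiles
  }
  t_r <- with_seed(seed, {
    grid_round(min(max(stats::rexp(1, 1 / 4), 0.5), 20), config$rate)
  })
  events <- data.frame(
    event_class = c("go_cue", "reward", "iti_start"),
    time_s = c(t_r, t_r, t_r)
  )
  thr <- resolve_threshold(config, profiles$M1)
  traces <- NULL
  components <- NULL
  if (synthesize) {
    gen_final <- events[events$event_class %in% KERNEL_EVENT_CLASSES, , drop = FALSE]
    sy <- synth_regions(profiles, regions, gen_final, mode, config,
                        t_end = t_r + config$post_s, seed = seed,
                        keep_components = keep_components)
    traces <- sy$traces
    components <- sy$components
  }
  trial_result(trial_index, "random_reward", "success", events, NA_real_,
               thr, t_r, traces = traces, components = components, seed = seed)
}
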
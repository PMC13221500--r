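#' Run one closed-loop session
#'
#' Presents scheduled trials until `n_success_target` successes (counting
#' both trial types) or the `max_trials` safety cap, advancing a session
#' clock (trial onset to trial conclusion, then the inter-trial interval),
#' and simulating post-reward lick trains. Every stochastic element is
#' controlled by `seed`; identical seeds and parameters give identical
#' sessions.
#'
#' @param agent an [agent_params()]
#' @param profiles named list of [region_profile()]s (must include `M1`)
#' @param config a [task_config()]
#' @param mode a [manipulation_mode()] or mode name
#' @param seed integer session seed
#' @param mouse_id mouse label
#' @param day day index
#' @param synthesize synthesise traces per trial (`TRUE`) or behavior-only
#' @param regions regions to synthesise
#' @param trial_variant `NULL` for the scheduled GO/NO-GO mix, or one trial
#'   type (e.g. `"GO_no_feedback"`, `"random_reward"`) presented on every
#'   trial (withdrawal and random-reward designs)
#' @param keep_components keep per-class generator components (tests)
#' @return an object of class `session_log`
#' @export
run_session <- function(agent, profiles, config = task_config(),
                        mode = "control", seed = 1, mouse_id = "m1",
                        day = 1L, synthesize = TRUE, regions = "M1",
                        trial_variant = NULL, keep_components = FALSE) {
  stopifnot(inherits(agent, "agent_params"), inherits(config, "task_config"))
  mode <- as_manipulation_mode(mode)
  if (!is.null(trial_variant) && !trial_variant %in% TRIAL_TYPES) {
    stop("unknown `trial_variant`: ", trial_variant, call. = FALSE)
  }
  sched <- schedule_trials(config$max_trials, config, derive_seed(seed, 0))
  mm <- apply_manipulation(agent, profiles, mode)
  agent_m <- mm$agent
  profiles_m <- mm$profiles
  trials <- vector("list", config$max_trials)
  onsets <- numeric(config$max_trials)
  clock <- 0
  n_success <- 0L
  n_presented <- 0L
  for (i in seq_len(config$max_trials)) {
    type_i <- if (is.null(trial_variant)) sched[i] else trial_variant
    tseed <- derive_seed(seed, i)
    tr <- if (type_i == "NOGO") {
      run_nogo_trial(agent_m, profiles_m, config, mode, seed = tseed,
                     synthesize = synthesize, regions = regions,
                     trial_index = i, keep_components = keep_components,
                     .preapplied = TRUE)
    } else if (type_i == "random_reward") {
      run_random_reward_trial(agent_m, profiles_m, config, mode, seed = tseed,
                              synthesize = synthesize, regions = regions,
                              trial_index = i, keep_components = keep_components,
                              .preapplied = TRUE)
    } else {
      run_go_trial(agent_m, profiles_m, config, mode, variant = type_i,
                   seed = tseed, synthesize = synthesize, regions = regions,
                   trial_index = i, keep_components = keep_components,
                   .preapplied = TRUE)
    }
    trials[[i]] <- tr
    onsets[i] <- clock
    clock <- clock + tr$conclude_s + config$iti
    n_presented <- i
    if (tr$outcome == "success") n_success <- n_success + 1L
    if (n_success >= config$n_success_target) break
  }
  trials <- trials[seq_len(n_presented)]
  onsets <- onsets[seq_len(n_presented)]
  capped <- n_success < config$n_success_target

  reward_abs <- unlist(lapply(seq_along(trials), function(i) {
    rt <- trials[[i]]$events$time_s[trials[[i]]$events$event_class == "reward"]
    rt + onsets[i]
  }))
  reward_abs <- sort(reward_abs)
  licks <- simulate_licks(reward_abs, agent_m, clock,
                          seed = derive_seed(seed, 999983))

  structure(
    list(
      mouse_id = mouse_id,
      day = as.integer(day),
      mode = mode$mode,
      cno_on = NA,
      config = config,
      seed = seed,
      trials = trials,
      trial_onsets = onsets,
      licks = licks,
      reward_times = reward_abs,
      duration_s = clock,
      n_presented = n_presented,
      n_success = n_success,
      capped = capped
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> mouse %s day %d (%s%s)\n", x$mouse_id, x$day,
              x$mode,
              if (isTRUE(x$cno_on)) ", CNO on" else ""))
  cat(sprintf("  %d trials presented, %d successes%s; %.0f s; %d licks\n",
              x$n_presented, x$n_success,
              if (x$capped) " (trial cap reached)" else "",
              x$duration_s, length(x$licks)))
  for (tt in c("GO", "NOGO")) {
    pres <- sum(vapply(x$trials, function(t) {
      t$trial_type != "random_reward" &&
        is_go_type(t$trial_type) == (tt == "GO")
    }, logical(1)))
    if (pres > 0) {
      cat(sprintf("  %s: success rate %.2f (%d presented)\n", tt,
                  success_rate(x, tt), pres))
    }
  }
  invisible(x)
}

#' Is a trial type a GO-family type?
#' @keywords internal
is_go_type <- function(trial_type) {
  trial_type %in% GO_VARIANTS
}

#' Flat event table of a session
#'
#' One row per logged event, with trial-relative and session-absolute
#' times; lick events are appended with class `"lick"`.
#'
#' @param log a `session_log`
#' @return data.frame with columns `mouse_id, day, mode, trial_index,
#'   trial_type, outcome, event_class, time_s, abs_time_s,
#'   response_time_s, threshold`
#' @export
session_events <- function(log) {
  stopifnot(inherits(log, "session_log"))
  rows <- lapply(seq_along(log$trials), function(i) {
    tr <- log$trials[[i]]
    data.frame(
      mouse_id = log$mouse_id, day = log$day, mode = log$mode,
      trial_index = tr$trial_index, trial_type = tr$trial_type,
      outcome = tr$outcome,
      event_class = tr$events$event_class,
      time_s = tr$events$time_s,
      abs_time_s = tr$events$time_s + log$trial_onsets[i],
      response_time_s = tr$response_time,
      threshold = tr$threshold_used,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  if (length(log$licks) > 0) {
    ev <- rbind(ev, data.frame(
      mouse_id = log$mouse_id, day = log$day, mode = log$mode,
      trial_index = NA_integer_, trial_type = NA_character_,
      outcome = NA_character_, event_class = "lick",
      time_s = NA_real_, abs_time_s = log$licks,
      response_time_s = NA_real_, threshold = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  ev[order(ev$abs_time_s), , drop = FALSE]
}
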
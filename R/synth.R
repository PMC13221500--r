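#' Synthesise one region's trace for a trial
#'
#' Builds a raw fluorescence trace as baseline + i.i.d. Gaussian noise +
#' the sum over ground-truth events of the region's event-class kernel.
#' Optogenetic manipulation modes multiply an event class's contribution
#' by the mode's gain, but only at samples inside the 1-s window locked to
#' the mode's target event; chemogenetic (tonic) gains are expected to be
#' already folded into the profile by [apply_manipulation()] and are not
#' re-applied here.
#'
#' The per-class components are returned alongside the composite trace so
#' tests can verify additivity and ablation exactly.
#'
#' @param profile a [region_profile()]
#' @param events data.frame with columns `event_class`, `time_s`; classes
#'   must be kernel-bearing classes (see [region_profile()]). Events may
#'   also fall before `t_start` (pre-cue ramps).
#' @param mode a [manipulation_mode()] or mode name (default `"control"`)
#' @param duration trace length in seconds (grid runs `t_start` to
#'   `t_start + duration`)
#' @param rate sampling rate in Hz (default 100)
#' @param seed integer seed for the noise stream, or `NULL`
#' @param t_start first sample time (default 0; negative values give a
#'   pre-trial baseline period)
#' @return list with `trace` (a [bci_trace()]), `components` (matrix, one
#'   column per event class), and `noise` (numeric vector)
#' @export
synthesize_trial_trace <- function(profile, events, mode = "control",
                                   duration, rate = 100, seed = NULL,
                                   t_start = 0) {
  stopifnot(inherits(profile, "region_profile"), duration > 0, rate > 0)
  mode <- as_manipulation_mode(mode)
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$event_class), KERNEL_EVENT_CLASSES)
    if (length(unknown) > 0) {
      stop("unknown event class in generator input: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  t <- seq(t_start, t_start + duration, by = 1 / rate)
  n <- length(t)
  comp <- matrix(0, nrow = n, ncol = length(KERNEL_EVENT_CLASSES),
                 dimnames = list(NULL, KERNEL_EVENT_CLASSES))
  for (cls in KERNEL_EVENT_CLASSES) {
    k <- profile$kernels[[cls]]
    if (k$amplitude == 0) next
    ev_t <- events$time_s[events$event_class == cls]
    for (e in ev_t) {
      comp[, cls] <- comp[, cls] + evaluate_kernel(k, t - e)
    }
  }
  # windowed (optogenetic) gains: scale the class contribution per sample
  if (!is.na(mode$window_event) && nrow(mode$signal_effects) > 0) {
    anchors <- events$time_s[events$event_class == mode$window_event]
    if (length(anchors) > 0) {
      in_win <- Reduce(`|`, lapply(anchors, function(a) {
        t >= a & t <= a + mode$window_s
      }))
      se <- mode$signal_effects[mode$signal_effects$region == profile$region_name, ,
                                drop = FALSE]
      for (i in seq_len(nrow(se))) {
        cls <- se$event_class[i]
        comp[in_win, cls] <- comp[in_win, cls] * se$gain[i]
      }
    }
  }
  noise <- if (profile$noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, profile$noise_sd))
  } else {
    numeric(n)
  }
  values <- profile$baseline_F + noise + rowSums(comp)
  list(
    trace = bci_trace(t, values, rate = rate, region = profile$region_name,
                      units = "au"),
    components = comp,
    noise = noise
  )
}

#' Simulate post-reward lick trains
#'
#' Licks form a homogeneous Poisson train at `lick_rate` inside the bout
#' `[reward, reward + lick_bout_duration]` following each reward, and occur
#' nowhere else. Bouts are truncated at the session end.
#'
#' @param reward_times sorted numeric vector of reward delivery times (s)
#' @param params an [agent_params()] (uses `lick_rate`, `lick_bout_duration`)
#' @param session_duration session length in seconds
#' @param seed integer seed or `NULL`
#' @return sorted numeric vector of lick timestamps (possibly empty)
#' @export
simulate_licks <- function(reward_times, params, session_duration, seed = NULL) {
  stopifnot(inherits(params, "agent_params"))
  if (length(reward_times) == 0 || params$lick_rate == 0) {
    return(numeric(0))
  }
  if (is.unsorted(reward_times)) {
    stop("`reward_times` must be sorted", call. = FALSE)
  }
  licks <- with_seed(seed, {
    out <- lapply(reward_times, function(r) {
      bout_end <- min(r + params$lick_bout_duration, session_duration)
      len <- bout_end - r
      if (len <= 0) return(numeric(0))
      n <- stats::rpois(1, params$lick_rate * len)
      sort(stats::runif(n, r, bout_end))
    })
    unlist(out)
  })
  sort(licks)
}
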
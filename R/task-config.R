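#' Stop-signal task configuration
#'
#' All paradigm constants of the volitional stop-signal task. Defaults are
#' the published paradigm: a 5,000-Hz GO cue opening a 30-s response
#' window; on NO-GO trials a 27,000-Hz stop cue 2 s after the GO cue,
#' followed by a 13-s below-threshold hold; a 10,000-Hz, 500-ms feedback
#' tone on success; reward 1 s after feedback onset; a 10-s inter-trial
#' interval; 67% GO / 33% NO-GO trial mix; sessions run to 50 successful
#' trials.
#'
#' @param go_cue_hz,stop_cue_hz,feedback_hz tone frequencies (labels only;
#'   no audio is synthesised)
#' @param feedback_duration feedback tone length, s
#' @param go_window GO response window, s
#' @param stop_delay GO-cue-to-stop-cue delay on NO-GO trials, s
#' @param hold_duration below-threshold hold required on NO-GO trials, s
#' @param reward_delay feedback-onset-to-reward delay, s
#' @param iti inter-trial interval, s
#' @param p_go probability that a scheduled trial is GO
#' @param n_success_target successful trials ending the session
#' @param max_trials safety cap on presented trials
#' @param threshold_rule either `list(type = "fixed", value = <dF/F>)` or
#'   `list(type = "adaptive", k = <SD multiplier>)` (threshold = pre-cue
#'   baseline mean + k SD of dF/F). The default is a fixed 0.5 dF/F:
#'   with the first-sample crossing rule, a noise-quantile threshold sits
#'   below the cue-evoked transient and would trigger spuriously (see the
#'   methods vignette).
#' @param scheduler `"bernoulli"` (i.i.d. draws, the default) or `"deck"`
#'   (shuffled fixed-count deck)
#' @param rate closed-loop simulation rate, Hz
#' @param pre_baseline_s pre-cue baseline recorded per trial, s (must not
#'   exceed `iti`)
#' @param post_s recording kept after the trial concludes, s
#' @return an object of class `task_config`
#' @export
task_config <- function(go_cue_hz = 5000,
                        stop_cue_hz = 27000,
                        feedback_hz = 10000,
                        feedback_duration = 0.5,
                        go_window = 30,
                        stop_delay = 2,
                        hold_duration = 13,
                        reward_delay = 1,
                        iti = 10,
                        p_go = 0.67,
                        n_success_target = 50,
                        max_trials = 500,
                        threshold_rule = list(type = "fixed", value = 0.5),
                        scheduler = "bernoulli",
                        rate = 100,
                        pre_baseline_s = 5,
                        post_s = 5) {
  cfg <- list(
    go_cue_hz = go_cue_hz, stop_cue_hz = stop_cue_hz, feedback_hz = feedback_hz,
    feedback_duration = feedback_duration, go_window = go_window,
    stop_delay = stop_delay, hold_duration = hold_duration,
    reward_delay = reward_delay, iti = iti, p_go = p_go,
    n_success_target = n_success_target, max_trials = max_trials,
    threshold_rule = threshold_rule, scheduler = scheduler, rate = rate,
    pre_baseline_s = pre_baseline_s, post_s = post_s
  )
  durs <- c("feedback_duration", "go_window", "stop_delay", "hold_duration",
            "reward_delay", "iti", "rate", "pre_baseline_s", "post_s")
  for (d in durs) {
    if (!is.numeric(cfg[[d]]) || !is.finite(cfg[[d]]) || cfg[[d]] <= 0) {
      stop(sprintf("`%s` must be a positive number", d), call. = FALSE)
    }
  }
  if (p_go < 0 || p_go > 1) stop("`p_go` must be in [0, 1]", call. = FALSE)
  if (n_success_target < 1) stop("`n_success_target` must be >= 1", call. = FALSE)
  if (max_trials < n_success_target) {
    stop("`max_trials` must be at least `n_success_target`", call. = FALSE)
  }
  if (anyDuplicated(c(go_cue_hz, stop_cue_hz, feedback_hz))) {
    stop("cue frequencies must be pairwise distinct", call. = FALSE)
  }
  if (!scheduler %in% c("bernoulli", "deck")) {
    stop("`scheduler` must be \"bernoulli\" or \"deck\"", call. = FALSE)
  }
  if (!is.list(threshold_rule) || is.null(threshold_rule$type) ||
      !threshold_rule$type %in% c("fixed", "adaptive")) {
    stop("`threshold_rule` must be list(type = \"fixed\", value = ...) or ",
         "list(type = \"adaptive\", k = ...)", call. = FALSE)
  }
  if (threshold_rule$type == "fixed" &&
      (is.null(threshold_rule$value) || threshold_rule$value <= 0)) {
    stop("fixed threshold rule needs a positive `value`", call. = FALSE)
  }
  if (threshold_rule$type == "adaptive" &&
      (is.null(threshold_rule$k) || threshold_rule$k <= 0)) {
    stop("adaptive threshold rule needs a positive `k`", call. = FALSE)
  }
  if (pre_baseline_s > iti) {
    stop("`pre_baseline_s` must not exceed `iti` (the pre-cue baseline is ",
         "recorded during the preceding inter-trial interval)", call. = FALSE)
  }
  structure(cfg, class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  cues: GO %g Hz, STOP %g Hz, feedback %g Hz (%g ms)\n",
              x$go_cue_hz, x$stop_cue_hz, x$feedback_hz,
              1000 * x$feedback_duration))
  cat(sprintf("  GO window %g s; stop delay %g s; hold %g s; reward delay %g s; ITI %g s\n",
              x$go_window, x$stop_delay, x$hold_duration, x$reward_delay, x$iti))
  cat(sprintf("  mix: %.0f%% GO; session target %d successes (cap %d); %s scheduler\n",
              100 * x$p_go, x$n_success_target, x$max_trials, x$scheduler))
  thr <- if (x$threshold_rule$type == "fixed") {
    sprintf("fixed %.3g dF/F", x$threshold_rule$value)
  } else {
    sprintf("baseline mean + %.3g SD", x$threshold_rule$k)
  }
  cat(sprintf("  threshold: %s; loop rate %g Hz\n", thr, x$rate))
  invisible(x)
}

#' GO-family trial variants
#' @keywords internal
GO_VARIANTS <- c("GO", "GO_no_cue", "GO_no_feedback", "GO_no_reward")

#' All trial types
#' @keywords internal
TRIAL_TYPES <- c(GO_VARIANTS, "NOGO", "random_reward")
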
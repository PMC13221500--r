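#' Known manipulation modes
#' @keywords internal
MANIPULATION_MODES <- c(
  "control", "hM3D", "hM4D",
  "eNpHR_at_feedback", "eNpHR_at_cue", "eNpHR_at_reward"
)

#' Chemogenetic / optogenetic manipulation model
#'
#' Encodes the effect of a circuit manipulation of the M2-innervated GPe
#' population as (i) multiplicative factors on the agent's behavioral
#' parameters and (ii) multiplicative gains on region kernel amplitudes.
#' For the optogenetic (`eNpHR_*`) modes the signal gains are applied only
#' inside a 1-s window time-locked to the targeted event, mirroring
#' transient time-locked inhibition; for the chemogenetic modes
#' (`hM3D`/`hM4D`, CNO-activated DREADDs) the gains act tonically on the
#' whole session.
#'
#' The default tables encode the direction of each reported contrast:
#' \describe{
#'   \item{hM3D}{GO success down, NO-GO inhibition up, licking down,
#'     GPe feedback transient suppressed; response time unchanged.}
#'   \item{hM4D}{behavior unchanged; M1 reward, STN feedback and GPe
#'     feedback transients suppressed.}
#'   \item{eNpHR_at_feedback}{GO success down, GO latency up, NO-GO
#'     inhibition up; STN feedback and reward transients suppressed inside
#'     the 1-s feedback-locked window.}
#'   \item{eNpHR_at_cue}{no behavioral or signal change (window locked to
#'     the GO cue).}
#'   \item{eNpHR_at_reward}{behavior unchanged; STN volitional, feedback
#'     and reward transients suppressed inside the 1-s reward-locked
#'     window.}
#' }
#'
#' @param mode one of `control`, `hM3D`, `hM4D`, `eNpHR_at_feedback`,
#'   `eNpHR_at_cue`, `eNpHR_at_reward`
#' @param strength scalar `>= 0` scaling the effect: every multiplicative
#'   factor `f` becomes `f^strength`, so `strength = 0` is equivalent to
#'   control and `strength = 1` is the default table. Useful for
#'   dose-response sweeps and parameter-recovery tests.
#' @return an object of class `manipulation_mode` with fields
#'   `mode`, `behavior_effects` (named factors on [agent_params()] fields),
#'   `signal_effects` (data.frame region/event_class/gain),
#'   `window_event` (event class anchoring the 1-s window, or `NA`), and
#'   `window_s` (window length, seconds)
#' @export
manipulation_mode <- function(mode = "control", strength = 1) {
  if (!is.character(mode) || length(mode) != 1 || !mode %in% MANIPULATION_MODES) {
    stop("unknown manipulation mode: ", paste(mode, collapse = ", "),
         " (must be one of ", paste(MANIPULATION_MODES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.finite(strength) || strength < 0) {
    stop("`strength` must be a non-negative number", call. = FALSE)
  }
  be <- c() # multiplicative factors on agent fields
  se <- data.frame(region = character(), event_class = character(),
                   gain = numeric(), stringsAsFactors = FALSE)
  window_event <- NA_character_
  if (mode == "hM3D") {
    be <- c(p_go_success = 0.6, p_inhibit = 1.4, lick_rate = 0.7)
    se <- data.frame(region = "GPe", event_class = "feedback", gain = 0.5)
  } else if (mode == "hM4D") {
    se <- data.frame(
      region = c("M1", "STN", "GPe"),
      event_class = c("reward", "feedback", "feedback"),
      gain = c(0.6, 0.5, 0.6)
    )
  } else if (mode == "eNpHR_at_feedback") {
    be <- c(p_go_success = 0.7, go_latency_mean = 1.3, p_inhibit = 1.3)
    se <- data.frame(
      region = c("STN", "STN"),
      event_class = c("feedback", "reward"),
      gain = c(0.5, 0.5)
    )
    window_event <- "feedback"
  } else if (mode == "eNpHR_at_cue") {
    window_event <- "go_cue"
  } else if (mode == "eNpHR_at_reward") {
    se <- data.frame(
      region = c("STN", "STN", "STN"),
      event_class = c("volitional_ramp", "feedback", "reward"),
      gain = c(0.6, 0.6, 0.6)
    )
    window_event <- "reward"
  }
  if (strength != 1) {
    be <- be^strength
    se$gain <- se$gain^strength
  }
  structure(
    list(
      mode = mode,
      behavior_effects = be,
      signal_effects = se,
      window_event = window_event,
      window_s = 1
    ),
    class = "manipulation_mode"
  )
}

#' @export
print.manipulation_mode <- function(x, ...) {
  cat(sprintf("<manipulation_mode> %s\n", x$mode))
  if (length(x$behavior_effects)) {
    cat("  behavior factors: ",
        paste(sprintf("%s x%.2g", names(x$behavior_effects), x$behavior_effects),
              collapse = ", "), "\n")
  }
  if (nrow(x$signal_effects)) {
    cat("  signal gains: ",
        paste(sprintf("%s/%s x%.2g", x$signal_effects$region,
                      x$signal_effects$event_class, x$signal_effects$gain),
              collapse = ", "), "\n")
  }
  if (!is.na(x$window_event)) {
    cat(sprintf("  applied inside %.3g-s window locked to %s\n",
                x$window_s, x$window_event))
  }
  invisible(x)
}

#' Coerce a mode name or object to a manipulation_mode
#' @keywords internal
as_manipulation_mode <- function(mode) {
  if (inherits(mode, "manipulation_mode")) mode else manipulation_mode(mode)
}

#' Apply a manipulation to agent parameters and region profiles
#'
#' Returns modified copies of the agent parameters (multiplicative
#' behavioral factors, probabilities capped at 1) and region profiles.
#' Tonic signal gains (chemogenetic modes) are folded into the kernel
#' amplitudes; time-windowed gains (optogenetic modes) are left to the
#' trace synthesiser, which applies them only inside the event-locked
#' window. `control` returns the inputs unchanged.
#'
#' @param agent an [agent_params()]
#' @param profiles named list of [region_profile()]s
#' @param mode a [manipulation_mode()] or a mode name
#' @return list with elements `agent` and `profiles`
#' @export
apply_manipulation <- function(agent, profiles, mode) {
  mode <- as_manipulation_mode(mode)
  stopifnot(inherits(agent, "agent_params"))
  a <- unclass(agent)
  for (field in names(mode$behavior_effects)) {
    a[[field]] <- a[[field]] * mode$behavior_effects[[field]]
    if (field %in% c("p_go_success", "p_inhibit", "premature_rate")) {
      a[[field]] <- min(a[[field]], 1)
    }
  }
  agent2 <- do.call(agent_params, a)
  profiles2 <- profiles
  se <- mode$signal_effects
  if (nrow(se) > 0 && is.na(mode$window_event)) { # tonic gains only
    for (i in seq_len(nrow(se))) {
      rg <- se$region[i]
      cl <- se$event_class[i]
      if (!is.null(profiles2[[rg]])) {
        k <- profiles2[[rg]]$kernels[[cl]]
        profiles2[[rg]]$kernels[[cl]] <-
          transient_kernel(k$amplitude * se$gain[i], k$rise_tau, k$decay_tau)
      }
    }
  }
  list(agent = agent2, profiles = profiles2)
}
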
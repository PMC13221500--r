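#' Event classes that carry a calcium transient
#' @keywords internal
KERNEL_EVENT_CLASSES <- c("go_cue", "stop_cue", "feedback", "reward", "volitional_ramp")

#' Region recording profile
#'
#' Describes how one recorded region (M1, GPe or STN) responds to task
#' events: a constant baseline fluorescence, i.i.d. Gaussian noise, and one
#' transient kernel per event class. An amplitude of zero encodes "this
#' region does not respond to this event".
#'
#' Baselines default to 1 a.u. so that kernel amplitudes read directly as
#' dF/F once traces are baseline-normalised.
#'
#' @param region_name one of `"M1"`, `"GPe"`, `"STN"`
#' @param baseline_F baseline fluorescence, arbitrary units, `> 0`
#' @param noise_sd standard deviation of additive Gaussian noise, `>= 0`
#' @param kernels named list with one [transient_kernel()] per event class
#'   (`go_cue`, `stop_cue`, `feedback`, `reward`, `volitional_ramp`)
#' @return an object of class `region_profile`
#' @seealso [default_region_profiles()]
#' @export
region_profile <- function(region_name, baseline_F = 1, noise_sd = 0.02, kernels) {
  if (!region_name %in% c("M1", "GPe", "STN")) {
    stop("`region_name` must be one of M1, GPe, STN", call. = FALSE)
  }
  if (!is.finite(baseline_F) || baseline_F <= 0) {
    stop("`baseline_F` must be positive", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  missing_cls <- setdiff(KERNEL_EVENT_CLASSES, names(kernels))
  if (length(missing_cls) > 0) {
    stop("`kernels` is missing event classes: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  for (k in kernels) {
    stopifnot(inherits(k, "transient_kernel"))
  }
  structure(
    list(
      region_name = region_name,
      baseline_F = baseline_F,
      noise_sd = noise_sd,
      kernels = kernels[KERNEL_EVENT_CLASSES]
    ),
    class = "region_profile"
  )
}

#' @export
print.region_profile <- function(x, ...) {
  amps <- vapply(x$kernels, function(k) k$amplitude, numeric(1))
  cat(sprintf("<region_profile> %s: baseline %.3g a.u., noise sd %.3g\n",
              x$region_name, x$baseline_F, x$noise_sd))
  cat("  kernel amplitudes (dF/F): ",
      paste(sprintf("%s=%.2g", names(amps), amps), collapse = ", "), "\n")
  invisible(x)
}

#' Default region profiles for M1, GPe and STN
#'
#' Amplitudes are free parameters of the generator (the paradigm defines
#' the component structure only qualitatively, as arrow-marked peaks on
#' representative traces); the defaults
#' are chosen for clear component separation: a volitional ramp in M1
#' large enough to cross the default control threshold with a wide noise
#' margin, mid-sized feedback and reward transients in all three regions,
#' cue transients in all regions, and a stop-cue transient only in the
#' basal-ganglia regions, where it is observed. Brief tone-evoked
#' transients (cues, feedback) decay faster than the slower reward and
#' volitional components.
#'
#' @param noise_sd Gaussian noise SD applied to every region
#' @return named list of [region_profile()] objects (`M1`, `GPe`, `STN`)
#' @export
default_region_profiles <- function(noise_sd = 0.02) {
  tone <- function(a) transient_kernel(a, rise_tau = 0.05, decay_tau = 0.4)
  slow <- function(a) transient_kernel(a, rise_tau = 0.1, decay_tau = 1.0)
  vol <- function(a) transient_kernel(a, rise_tau = 0.3, decay_tau = 1.0)
  list(
    M1 = region_profile("M1", 1, noise_sd, list(
      go_cue = tone(0.30), stop_cue = tone(0.00), feedback = tone(0.50),
      reward = slow(0.80), volitional_ramp = vol(0.90)
    )),
    GPe = region_profile("GPe", 1, noise_sd, list(
      go_cue = tone(0.25), stop_cue = tone(0.30), feedback = tone(0.60),
      reward = slow(0.70), volitional_ramp = vol(0.60)
    )),
    STN = region_profile("STN", 1, noise_sd, list(
      go_cue = tone(0.25), stop_cue = tone(0.30), feedback = tone(0.55),
      reward = slow(0.65), volitional_ramp = vol(0.55)
    ))
  )
}

#' Behavioral parameters of the simulated mouse agent
#'
#' The agent abstracts a trained head-fixed mouse: on GO trials it drives
#' the M1 signal over threshold with probability `p_go_success`, starting
#' its volitional ramp `go_latency` seconds after the cue and crossing
#' `ramp_duration` seconds later; on NO-GO trials it withholds with
#' probability `p_inhibit`, crosses prematurely (before the stop cue) with
#' probability `premature_rate`, and licks at `lick_rate` Hz for
#' `lick_bout_duration` seconds after each reward.
#'
#' Defaults emulate a mouse that has passed the 85--100% three-day
#' training criterion on both trial types.
#'
#' @param p_go_success probability of a successful GO response
#' @param go_latency_mean,go_latency_sd Gaussian latency (s) from GO cue to
#'   ramp onset
#' @param ramp_duration seconds from ramp onset to intended threshold crossing
#' @param p_inhibit probability of withholding after the stop cue
#' @param premature_rate probability of crossing before the stop cue on NO-GO
#' @param lick_rate licks per second during a post-reward bout
#' @param lick_bout_duration bout length in seconds
#' @return an object of class `agent_params`
#' @export
agent_params <- function(p_go_success = 0.88,
                         go_latency_mean = 4,
                         go_latency_sd = 1.5,
                         ramp_duration = 2,
                         p_inhibit = 0.88,
                         premature_rate = 0.03,
                         lick_rate = 6,
                         lick_bout_duration = 2) {
  p <- list(
    p_go_success = p_go_success,
    go_latency_mean = go_latency_mean,
    go_latency_sd = go_latency_sd,
    ramp_duration = ramp_duration,
    p_inhibit = p_inhibit,
    premature_rate = premature_rate,
    lick_rate = lick_rate,
    lick_bout_duration = lick_bout_duration
  )
  for (pr in c("p_go_success", "p_inhibit", "premature_rate")) {
    if (!is.finite(p[[pr]]) || p[[pr]] < 0 || p[[pr]] > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", pr), call. = FALSE)
    }
  }
  for (pr in c("go_latency_mean", "ramp_duration", "lick_bout_duration")) {
    if (!is.finite(p[[pr]]) || p[[pr]] <= 0) {
      stop(sprintf("`%s` must be positive", pr), call. = FALSE)
    }
  }
  if (p$go_latency_sd < 0 || p$lick_rate < 0) {
    stop("`go_latency_sd` and `lick_rate` must be non-negative", call. = FALSE)
  }
  structure(p, class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n")
  cat(sprintf("  GO: p_success %.2f, latency %.2f +/- %.2f s, ramp %.2f s\n",
              x$p_go_success, x$go_latency_mean, x$go_latency_sd, x$ramp_duration))
  cat(sprintf("  NO-GO: p_inhibit %.2f, premature rate %.2f\n",
              x$p_inhibit, x$premature_rate))
  cat(sprintf("  licks: %.1f /s for %.1f s per reward\n",
              x$lick_rate, x$lick_bout_duration))
  invisible(x)
}
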
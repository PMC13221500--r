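#' Moving-average smoothing of a trace
#'
#' Smooths a fluorescence trace with a centered moving-average filter: the
#' output sample at each step is the arithmetic mean of the input samples
#' whose times fall inside the span centered on the output time. Edge
#' windows are truncated, not padded, so constant signals stay constant at
#' the edges. The output grid steps every `step_ms` from the first input
#' sample, i.e. the output rate is `1000 / step_ms` Hz.
#'
#' @param trace a [bci_trace()]
#' @param span_ms averaging span, ms (`>= step_ms`)
#' @param step_ms output step, ms
#' @return a smoothed [bci_trace()] at the new rate
#' @export
moving_average <- function(trace, span_ms = 20, step_ms = 10) {
  stopifnot(inherits(trace, "bci_trace"))
  if (step_ms <= 0 || span_ms < step_ms) {
    stop("need span_ms >= step_ms > 0", call. = FALSE)
  }
  dt <- 1 / trace$rate
  if (span_ms / 1000 < dt - 1e-9) {
    stop("`span_ms` is shorter than one sample period of the trace",
         call. = FALSE)
  }
  step <- step_ms / 1000
  half <- span_ms / 2000
  t0 <- trace$times[1]
  t1 <- trace$times[length(trace$times)]
  out_t <- seq(t0, t1, by = step)
  # window [t - half, t + half] on a uniform grid: index bounds via rounding
  # (epsilon guards against floating-point boundary misses)
  eps <- 1e-9
  lo <- pmax(1, ceiling((out_t - half - t0) / dt - eps) + 1)
  hi <- pmin(length(trace$times), floor((out_t + half - t0) / dt + eps) + 1)
  cs <- c(0, cumsum(trace$values))
  vals <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  bci_trace(out_t, vals, rate = 1000 / step_ms, region = trace$region,
            units = trace$units)
}

#' Convert a raw fluorescence trace to dF/F
#'
#' `dF/F = (F - F0) / F0`, with `F0` the baseline fluorescence at the time
#' of the auditory cue: the mean of the samples within `baseline_ms`
#' milliseconds after `cue_time` (the window is interpreted as immediately
#' following cue onset).
#'
#' @param trace a raw-fluorescence [bci_trace()]
#' @param cue_time cue onset in seconds (trace time base)
#' @param baseline_ms baseline window length, ms
#' @return a dF/F [bci_trace()]
#' @export
compute_dff <- function(trace, cue_time, baseline_ms = 10) {
  stopifnot(inherits(trace, "bci_trace"))
  if (trace$units == "dff") {
    stop("trace is already dF/F", call. = FALSE)
  }
  eps <- 1e-9
  in_base <- trace$times >= cue_time - eps &
    trace$times <= cue_time + baseline_ms / 1000 + eps
  if (!any(in_base)) {
    stop("baseline window [cue_time, cue_time + baseline_ms] contains no samples",
         call. = FALSE)
  }
  f0 <- mean(trace$values[in_base])
  if (f0 <= 0) {
    stop("degenerate baseline: F0 <= 0 (fluorescence must be positive)",
         call. = FALSE)
  }
  bci_trace(trace$times, (trace$values - f0) / f0, rate = trace$rate,
            region = trace$region, units = "dff")
}

#' Align a trace segment to an event
#'
#' Extracts the window `[event_time - pre, event_time + post]` on a
#' relative time base (0 = the alignment event), without resampling.
#' Windows that extend beyond the trace are truncated and flagged.
#'
#' @param trace a [bci_trace()] (typically dF/F)
#' @param event_time absolute event time, seconds
#' @param pre seconds before the event (default 15, the reward-aligned
#'   display convention; 10 in the optogenetic experiments)
#' @param post seconds after the event
#' @return an object of class `aligned_segment`: list with `times`
#'   (relative), `values`, `rate`, `region`, `alignment_time`, `pre`,
#'   `post`, `truncated`
#' @export
align_to_event <- function(trace, event_time, pre = 15, post = 10) {
  stopifnot(inherits(trace, "bci_trace"), pre >= 0, post >= 0)
  t0 <- trace$times[1]
  t1 <- trace$times[length(trace$times)]
  if (event_time < t0 || event_time > t1) {
    stop("alignment event lies outside the trace", call. = FALSE)
  }
  eps <- 1e-9
  keep <- trace$times >= event_time - pre - eps &
    trace$times <= event_time + post + eps
  truncated <- (event_time - pre < t0 - eps) || (event_time + post > t1 + eps)
  structure(
    list(
      times = trace$times[keep] - event_time,
      values = trace$values[keep],
      rate = trace$rate,
      region = trace$region,
      alignment_time = event_time,
      pre = pre, post = post,
      truncated = truncated
    ),
    class = "aligned_segment"
  )
}

#' @export
print.aligned_segment <- function(x, ...) {
  cat(sprintf("<aligned_segment> %s: %d samples, t in [%.2f, %.2f] s%s\n",
              x$region, length(x$times), min(x$times), max(x$times),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Default component peak-search windows
#'
#' Windows are relative to each component's own logged event time: cue and
#' feedback transients are sharp (1-s windows from onset), the reward
#' transient is slower (3 s), and the volitional signal is the build-up
#' preceding the threshold crossing, so its window ends at the crossing.
#' The paradigm identifies the components only qualitatively (arrow-marked
#' peaks on representative traces); the numeric windows are package
#' defaults and fully configurable.
#'
#' @return named list of `c(lo, hi)` offsets in seconds, anchored at the
#'   event classes `go_cue`, `stop_cue`, `feedback`, `reward` and (for the
#'   volitional component) `crossing`
#' @export
default_component_windows <- function() {
  list(
    go_cue = c(0, 1),
    stop_cue = c(0, 1),
    feedback = c(0, 1),
    reward = c(0, 3),
    volitional = c(-2, 0)
  )
}

# Event class anchoring each component window
component_anchor <- function(component) {
  switch(component,
    volitional = "crossing",
    component
  )
}

#' Extract per-component peak dF/F from an aligned segment
#'
#' For each requested component, the peak is the maximum of the segment
#' restricted to the component's window anchored at the trial's logged
#' event time (the volitional component is anchored at the threshold
#' crossing). Components whose anchoring event is absent from the trial
#' (withdrawal variants, failed trials) yield `NA`; windows that fall
#' partly outside the segment are truncated and flagged.
#'
#' @param segment an [align_to_event()] segment
#' @param trial_events data.frame with columns `event_class`, `time_s`
#'   (absolute times on the trace time base used for alignment)
#' @param windows named list of `c(lo, hi)` second offsets, as
#'   [default_component_windows()]
#' @return data.frame with columns `component, peak_dff, window_lo,
#'   window_hi, truncated` (one row per requested component)
#' @export
extract_component_peaks <- function(segment, trial_events,
                                    windows = default_component_windows()) {
  stopifnot(inherits(segment, "aligned_segment"))
  eps <- 1e-9
  rows <- lapply(names(windows), function(comp) {
    w <- windows[[comp]]
    if (length(w) != 2 || w[2] <= w[1]) {
      stop("window for component ", comp, " must be c(lo, hi) with hi > lo",
           call. = FALSE)
    }
    anchor <- component_anchor(comp)
    ev <- trial_events$time_s[trial_events$event_class == anchor]
    if (length(ev) == 0 && comp == "feedback") {
      # feedback is crossing-locked; when the tone is withheld (withdrawal
      # variant) the window is anchored at the crossing so the residual
      # signal in the would-be feedback window remains measurable
      ev <- trial_events$time_s[trial_events$event_class == "crossing"]
    }
    if (length(ev) == 0) {
      return(data.frame(component = comp, peak_dff = NA_real_,
                        window_lo = NA_real_, window_hi = NA_real_,
                        truncated = NA))
    }
    rel <- ev[1] - segment$alignment_time
    lo <- rel + w[1]
    hi <- rel + w[2]
    keep <- segment$times >= lo - eps & segment$times <= hi + eps
    truncated <- lo < min(segment$times) - eps || hi > max(segment$times) + eps
    peak <- if (any(keep)) max(segment$values[keep]) else NA_real_
    data.frame(component = comp, peak_dff = peak,
               window_lo = lo, window_hi = hi, truncated = truncated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tidy per-trial component peak table for a session or experiment
#'
#' Runs the full per-trial photometry pipeline on synthesised traces:
#' moving-average smoothing (20-ms span, 10-ms step), dF/F conversion with
#' the cue-locked baseline, alignment, and component peak extraction.
#' Trials without traces are skipped.
#'
#' @param x a `session_log` or `bci_experiment` (with synthesised traces)
#' @param windows component windows, as [default_component_windows()]
#' @param smooth apply the moving-average filter first (default `TRUE`)
#' @param span_ms,step_ms smoothing parameters
#' @return data.frame with columns `mouse_id, day, mode, trial_index,
#'   trial_type, outcome, region, component, peak_dff, window_lo,
#'   window_hi, truncated`
#' @export
peak_table <- function(x, windows = default_component_windows(),
                       smooth = TRUE, span_ms = 20, step_ms = 10) {
  if (inherits(x, "bci_experiment")) {
    out <- lapply(x$sessions, peak_table, windows = windows, smooth = smooth,
                  span_ms = span_ms, step_ms = step_ms)
    return(do.call(rbind, out))
  }
  stopifnot(inherits(x, "session_log"))
  rows <- list()
  for (tr in x$trials) {
    if (is.null(tr$traces)) next
    # cue-locked F0 at trial onset (t = 0 also for the no-cue variant)
    for (rg in names(tr$traces)) {
      raw <- tr$traces[[rg]]
      if (smooth) raw <- moving_average(raw, span_ms, step_ms)
      dff <- compute_dff(raw, cue_time = 0)
      align_t <- event_time(tr, "reward")
      if (is.na(align_t)) align_t <- 0
      seg <- align_to_event(dff, align_t,
                            pre = align_t - dff$times[1],
                            post = dff$times[length(dff$times)] - align_t)
      pk <- extract_component_peaks(seg, tr$events, windows)
      pk$mouse_id <- x$mouse_id
      pk$day <- x$day
      pk$mode <- x$mode
      pk$trial_index <- tr$trial_index
      pk$trial_type <- tr$trial_type
      pk$outcome <- tr$outcome
      pk$region <- rg
      rows[[length(rows) + 1]] <- pk
    }
  }
  if (length(rows) == 0) {
    return(NULL)
  }
  out <- do.call(rbind, rows)
  out[, c("mouse_id", "day", "mode", "trial_index", "trial_type", "outcome",
          "region", "component", "peak_dff", "window_lo", "window_hi",
          "truncated")]
}
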
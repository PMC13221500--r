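#' Stereotyped calcium transient kernel
#'
#' A peak-normalised difference-of-exponentials waveform used to model the
#' stereotyped event-locked transients of a genetically encoded calcium
#' indicator (fast rise, slow decay). The kernel is zero at onset, rises
#' with time constant `rise_tau`, decays with `decay_tau`, and is scaled so
#' that its maximum equals `amplitude` (in dF/F units relative to a unit
#' baseline).
#'
#' @param amplitude peak height, dF/F units, `>= 0`. Zero means the region
#'   does not respond to the event class.
#' @param rise_tau rise time constant in seconds, `0 < rise_tau < decay_tau`
#' @param decay_tau decay time constant in seconds
#' @return an object of class `transient_kernel`
#' @examples
#' k <- transient_kernel(1, 0.1, 1.0)
#' evaluate_kernel(k, seq(0, 3, by = 0.01))
#' @export
transient_kernel <- function(amplitude, rise_tau = 0.1, decay_tau = 1.0) {
  stopifnot(length(amplitude) == 1, length(rise_tau) == 1, length(decay_tau) == 1)
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("`amplitude` must be a finite non-negative number", call. = FALSE)
  }
  if (!is.finite(rise_tau) || !is.finite(decay_tau) ||
      rise_tau <= 0 || decay_tau <= 0) {
    stop("`rise_tau` and `decay_tau` must be positive", call. = FALSE)
  }
  if (rise_tau >= decay_tau) {
    stop("`rise_tau` must be strictly smaller than `decay_tau`", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, rise_tau = rise_tau, decay_tau = decay_tau),
    class = "transient_kernel"
  )
}

#' @export
print.transient_kernel <- function(x, ...) {
  cat(sprintf(
    "<transient_kernel> amplitude %.3g dF/F, rise %.3g s, decay %.3g s\n",
    x$amplitude, x$rise_tau, x$decay_tau
  ))
  invisible(x)
}

#' Time of the kernel maximum
#'
#' Closed form argmax of `exp(-t/decay) - exp(-t/rise)`.
#'
#' @param kernel a [transient_kernel()]
#' @return peak time in seconds
#' @export
kernel_peak_time <- function(kernel) {
  r <- kernel$rise_tau
  d <- kernel$decay_tau
  r * d / (d - r) * log(d / r)
}

#' Evaluate a transient kernel on a time grid
#'
#' Returns `amplitude * (exp(-t/decay_tau) - exp(-t/rise_tau))`, rescaled so
#' the maximum over `t >= 0` equals `amplitude`. Times before onset
#' (`t < 0`) evaluate to zero, so the kernel can be shifted onto arbitrary
#' event times by evaluating at `t - event_time`.
#'
#' @param kernel a [transient_kernel()]
#' @param t numeric vector of times in seconds
#' @return numeric vector of dF/F values, same length as `t`
#' @export
evaluate_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "transient_kernel"), is.numeric(t))
  if (length(t) == 0) {
    return(numeric(0))
  }
  if (kernel$amplitude == 0) {
    return(numeric(length(t)))
  }
  tp <- kernel_peak_time(kernel)
  norm <- exp(-tp / kernel$decay_tau) - exp(-tp / kernel$rise_tau)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- kernel$amplitude *
    (exp(-t[pos] / kernel$decay_tau) - exp(-t[pos] / kernel$rise_tau)) / norm
  out
}

#' First grid time at which a noiseless kernel reaches a level
#'
#' Used by the task engine to place the volitional ramp so that the
#' closed-loop threshold crossing lands on an intended time: the offset is
#' the first sample (on a `rate`-Hz grid starting at 0) where the kernel
#' value reaches `level`. Returns `NA` when the kernel never reaches the
#' level (amplitude below threshold).
#'
#' @param kernel a [transient_kernel()]
#' @param level dF/F level to reach
#' @param rate grid rate in Hz
#' @return offset in seconds, or `NA_real_`
#' @keywords internal
kernel_crossing_offset <- function(kernel, level, rate) {
  if (kernel$amplitude < level) {
    return(NA_real_)
  }
  t <- seq(0, kernel_peak_time(kernel) + kernel$decay_tau, by = 1 / rate)
  v <- evaluate_kernel(kernel, t)
  i <- which(v >= level)
  if (length(i) == 0) NA_real_ else t[i[1]]
}
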
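#' Uniformly sampled fluorescence trace
#'
#' Container for one region's photometry time series: a uniform time grid,
#' sample values (raw fluorescence in arbitrary units, or dF/F after
#' conversion), the sampling rate, and the region name.
#'
#' @param times numeric vector of sample times in seconds, uniformly spaced
#' @param values numeric vector of samples, same length as `times`
#' @param rate sampling rate in Hz; inferred from `times` when `NULL`
#' @param region region label (e.g. `"M1"`)
#' @param units `"au"` (raw fluorescence) or `"dff"`
#' @return an object of class `bci_trace`
#' @export
bci_trace <- function(times, values, rate = NULL, region = "M1", units = "au") {
  stopifnot(is.numeric(times), is.numeric(values), length(times) == length(values))
  if (!units %in% c("au", "dff")) {
    stop("`units` must be \"au\" or \"dff\"", call. = FALSE)
  }
  if (length(times) >= 2) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-9) {
      stop("`times` must be uniformly spaced (tolerance 1e-9 s)", call. = FALSE)
    }
    if (is.null(rate)) {
      rate <- 1 / mean(dt)
    } else if (abs(1 / rate - mean(dt)) > 1e-9) {
      stop("`rate` does not match the spacing of `times`", call. = FALSE)
    }
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(times = times, values = values, rate = rate,
         region = region, units = units),
    class = "bci_trace"
  )
}

#' @export
print.bci_trace <- function(x, ...) {
  cat(sprintf("<bci_trace> %s: %d samples at %.6g Hz [%s], t in [%.3g, %.3g] s\n",
              x$region, length(x$times),
              if (is.null(x$rate)) NA_real_ else x$rate,
              x$units,
              if (length(x$times)) min(x$times) else NA_real_,
              if (length(x$times)) max(x$times) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.bci_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values,
             region = x$region, units = x$units)
}
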
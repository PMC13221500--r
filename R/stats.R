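#' Per-type success rate of a session
#'
#' Successes divided by presented trials of the requested type, following
#' the paradigm's definition (successful GO trials relative to total GO
#' trials, and similarly for NO-GO).
#'
#' @param log a `session_log`
#' @param trial_type `"GO"` (any GO-family variant) or `"NOGO"`
#' @return fraction in `[0, 1]`
#' @export
success_rate <- function(log, trial_type = c("GO", "NOGO")) {
  stopifnot(inherits(log, "session_log"))
  trial_type <- match.arg(trial_type)
  sel <- vapply(log$trials, function(tr) {
    is_go_type(tr$trial_type) == (trial_type == "GO") &&
      tr$trial_type != "random_reward"
  }, logical(1))
  if (!any(sel)) {
    stop("no presented trials of type ", trial_type, call. = FALSE)
  }
  succ <- vapply(log$trials[sel], function(tr) tr$outcome == "success", logical(1))
  mean(succ)
}

#' Response times of a session
#'
#' One value per trial with a threshold crossing, measured from trial
#' onset. Successful NO-GO trials have no crossing by definition, so
#' NO-GO response times exist only for error trials.
#'
#' @param log a `session_log`
#' @param trial_type `"GO"` or `"NOGO"`
#' @param outcome `"success"`, `"failure"` or `"all"` (default: success
#'   for GO, failure for NO-GO — the paradigm's reported endpoints)
#' @return numeric vector of seconds (possibly empty)
#' @export
response_times <- function(log, trial_type = c("GO", "NOGO"),
                           outcome = NULL) {
  stopifnot(inherits(log, "session_log"))
  trial_type <- match.arg(trial_type)
  if (is.null(outcome)) {
    outcome <- if (trial_type == "GO") "success" else "failure"
  }
  rts <- vapply(log$trials, function(tr) {
    ok <- is_go_type(tr$trial_type) == (trial_type == "GO") &&
      tr$trial_type != "random_reward" &&
      (outcome == "all" || tr$outcome == outcome)
    if (ok) tr$response_time else NA_real_
  }, numeric(1))
  rts[!is.na(rts)]
}

#' Total licks of a session
#' @param log a `session_log`
#' @return lick count
#' @export
total_licks <- function(log) {
  stopifnot(inherits(log, "session_log"))
  length(log$licks)
}

#' Training eligibility criterion
#'
#' A mouse is eligible once it achieves a correct response rate of
#' 85--100% over three consecutive days.
#'
#' @param daily_rates numeric vector of daily correct-response rates in
#'   `[0, 1]`, in day order (at least 3 days)
#' @return `TRUE` if some run of three consecutive days all have rate
#'   `>= 0.85`
#' @export
training_criterion <- function(daily_rates) {
  if (length(daily_rates) < 3) {
    stop("need at least 3 daily rates", call. = FALSE)
  }
  if (any(daily_rates < 0 | daily_rates > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  ok <- daily_rates >= 0.85
  any(ok[-c(length(ok) - 1, length(ok))] &
        ok[-c(1, length(ok))] &
        ok[-c(1, 2)])
}

#' Unpaired two-tailed Student's t test (pooled variance)
#'
#' Classical Student's t with pooled variance and `n_a + n_b - 2` degrees
#' of freedom. When both groups are constant: equal means give `t = 0,
#' p = 1`; unequal means are flagged degenerate (infinite evidence under
#' the model). Welch's unequal-variance form is available via
#' `var_equal = FALSE`.
#'
#' @param a,b numeric vectors (each `n >= 2`, finite)
#' @param var_equal pooled variance (default `TRUE`, the classical form)
#' @return list with `statistic`, `df`, `p_value`, `degenerate`
#' @export
unpaired_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p_value = 1, degenerate = FALSE))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p_value = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Two-tailed Mann-Whitney U test
#'
#' Reports `U = min(U_a, U_b)` and the two-tailed p-value: exact by
#' enumeration when the combined sample size is at most 16 and there are
#' no ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric vectors (each `n >= 1`)
#' @return list with `U`, `p_value`, `exact`
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    stop("each group needs at least 1 value", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (na + nb) <= 16 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  u_a <- unname(ht$statistic) # rank-sum U for sample a
  u <- min(u_a, na * nb - u_a)
  list(U = u, p_value = ht$p.value, exact = exact)
}

#' Significance stars
#'
#' The reporting convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p p-value
#' @return `""`, `"*"`, `"**"` or `"***"`
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Behavioral / signal endpoints
#' @keywords internal
ENDPOINTS <- c("go_success", "nogo_success", "go_rt", "nogo_error_rt",
               "total_licks")

# Endpoint value for one session; peaks handled separately.
session_endpoint <- function(log, endpoint) {
  switch(endpoint,
    go_success = success_rate(log, "GO"),
    nogo_success = success_rate(log, "NOGO"),
    go_rt = mean(response_times(log, "GO")),
    nogo_error_rt = mean(response_times(log, "NOGO")),
    total_licks = total_licks(log),
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  )
}

#' Per-mouse endpoint summaries for an experiment
#'
#' Averages the endpoint across each mouse's included sessions (the three
#' CNO-on days for chemogenetic designs, all sessions otherwise), giving
#' exactly one independent data point per mouse.
#'
#' Behavioral endpoints: `go_success`, `nogo_success`, `go_rt` (successful
#' GO response time), `nogo_error_rt` (error-trial NO-GO response time),
#' `total_licks` (per session, averaged over sessions). Signal endpoints
#' take the form `"peak:<region>:<component>"` (e.g. `"peak:GPe:feedback"`)
#' and require sessions synthesised with traces; per-trial peaks are
#' averaged within and then across sessions.
#'
#' @param experiment a `bci_experiment`
#' @param endpoint endpoint name
#' @param windows component windows for peak endpoints
#' @return data.frame with columns `group, mouse_id, value`
#' @export
mouse_summary <- function(experiment, endpoint,
                          windows = default_component_windows()) {
  stopifnot(inherits(experiment, "bci_experiment"))
  inc <- included_sessions(experiment)
  if (length(inc) == 0) {
    stop("no sessions match the design's inclusion rule", call. = FALSE)
  }
  meta <- experiment$meta[experiment$meta$session %in% inc, , drop = FALSE]
  is_peak <- grepl("^peak:", endpoint)
  if (is_peak) {
    parts <- strsplit(endpoint, ":")[[1]]
    if (length(parts) != 3) {
      stop("peak endpoints are \"peak:<region>:<component>\"", call. = FALSE)
    }
    region <- parts[2]
    component <- parts[3]
  }
  rows <- lapply(split(meta, meta$mouse_id), function(mm) {
    vals <- vapply(mm$session, function(si) {
      log <- experiment$sessions[[si]]
      if (!is_peak) {
        return(session_endpoint(log, endpoint))
      }
      pk <- peak_table(log, windows = windows)
      if (is.null(pk)) {
        stop("peak endpoint requires sessions synthesised with traces",
             call. = FALSE)
      }
      sel <- pk$region == region & pk$component == component & !is.na(pk$peak_dff)
      if (!any(sel)) NA_real_ else mean(pk$peak_dff[sel])
    }, numeric(1))
    data.frame(group = mm$group[1], mouse_id = mm$mouse_id[1],
               value = mean(vals, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$mouse_id), , drop = FALSE]
}

#' Compare manipulation groups against control on one endpoint
#'
#' Builds the per-mouse summary (one independent point per mouse) and
#' tests every non-control group against the control group. `test =
#' "auto"` uses the Mann-Whitney U test for bounded success-rate
#' endpoints and Student's t for continuous endpoints (times, licks,
#' peaks); `"both"` runs the two tests and calls a contrast significant
#' only when they agree at the 0.05 level (disagreements are thereby
#' flagged conservative).
#'
#' @param experiment a `bci_experiment`
#' @param endpoint endpoint name (see [mouse_summary()])
#' @param test `"auto"`, `"student_t"`, `"mann_whitney_u"` or `"both"`
#' @param control name of the control group (default `"control"`, or the
#'   first group)
#' @param windows component windows for peak endpoints
#' @param alpha significance level for the `significant` column
#' @return data.frame with one row per comparison: `endpoint, group,
#'   n_control, n_group, mean_control, mean_group, test, statistic,
#'   p_value, p_t, p_u, stars, significant`
#' @export
summarize_and_compare <- function(experiment, endpoint, test = "auto",
                                  control = NULL,
                                  windows = default_component_windows(),
                                  alpha = 0.05) {
  stopifnot(test %in% c("auto", "student_t", "mann_whitney_u", "both"))
  ms <- mouse_summary(experiment, endpoint, windows = windows)
  groups <- unique(ms$group)
  if (is.null(control)) {
    control <- if ("control" %in% groups) "control" else groups[1]
  }
  if (!control %in% groups) {
    stop("control group ", control, " not present", call. = FALSE)
  }
  ctrl_vals <- ms$value[ms$group == control]
  if (length(ctrl_vals) < 2) {
    stop("control group has fewer than 2 mice", call. = FALSE)
  }
  if (test == "auto") {
    test <- if (endpoint %in% c("go_success", "nogo_success")) {
      "mann_whitney_u"
    } else {
      "student_t"
    }
  }
  rows <- lapply(setdiff(groups, control), function(g) {
    gv <- ms$value[ms$group == g]
    if (length(gv) < 2) {
      stop("group ", g, " has fewer than 2 mice", call. = FALSE)
    }
    p_t <- NA_real_
    p_u <- NA_real_
    if (test %in% c("student_t", "both")) {
      p_t <- unpaired_t_test(ctrl_vals, gv)$p_value
    }
    if (test %in% c("mann_whitney_u", "both")) {
      p_u <- mann_whitney_u(ctrl_vals, gv)$p_value
    }
    if (test == "student_t") {
      ht <- unpaired_t_test(ctrl_vals, gv)
      stat <- ht$statistic
      p <- ht$p_value
      sig <- p < alpha
    } else if (test == "mann_whitney_u") {
      ht <- mann_whitney_u(ctrl_vals, gv)
      stat <- ht$U
      p <- ht$p_value
      sig <- p < alpha
    } else {
      stat <- NA_real_
      p <- max(p_t, p_u) # conservative summary of the concordance rule
      sig <- (p_t < alpha) && (p_u < alpha)
    }
    data.frame(
      endpoint = endpoint, group = g,
      n_control = length(ctrl_vals), n_group = length(gv),
      mean_control = mean(ctrl_vals), mean_group = mean(gv),
      test = test, statistic = stat, p_value = p, p_t = p_t, p_u = p_u,
      stars = significance_stars(p), significant = sig,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
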
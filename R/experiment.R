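#' Experiment designs
#' @keywords internal
EXPERIMENT_DESIGNS <- c(
  "chemogenetic", "optogenetic_feedback", "optogenetic_cue",
  "optogenetic_reward", "random_reward", "withdrawal"
)

#' Run a multi-mouse, multi-day experiment
#'
#' Reproduces the study designs as seeded simulations:
#' \describe{
#'   \item{chemogenetic}{control / hM4D / hM3D groups (default n = 6
#'     each) over 6 days; CNO is administered on alternate days (days 2,
#'     4, 6), so each mouse has exactly three CNO-on sessions, which are
#'     the sessions included in group summaries. The manipulation is
#'     active only on CNO days and only in the DREADD groups.}
#'   \item{optogenetic_feedback / optogenetic_cue / optogenetic_reward}{
#'     control (n = 6) vs eNpHR (n = 7) groups; 1-s time-locked
#'     suppression applied on every trial of every session.}
#'   \item{random_reward}{one group of sessions of random-reward trials
#'     (cue co-played with a signal-decoupled reward).}
#'   \item{withdrawal}{one group per GO variant (`GO`, `GO_no_cue`,
#'     `GO_no_feedback`, `GO_no_reward`), used for component-ablation
#'     analyses.}
#' }
#'
#' Every session gets a distinct seed derived from `seed`, so the whole
#' experiment is reproducible and groups are statistically independent.
#'
#' @param design one of `chemogenetic`, `optogenetic_feedback`,
#'   `optogenetic_cue`, `optogenetic_reward`, `random_reward`, `withdrawal`
#' @param agent an [agent_params()] shared by all mice
#' @param profiles named list of [region_profile()]s
#' @param config a [task_config()]
#' @param n_mice named integer vector of group sizes, or `NULL` for the
#'   design's published sizes
#' @param days number of days, or `NULL` for the design default
#' @param seed experiment seed
#' @param strength manipulation effect strength (see [manipulation_mode()])
#' @param synthesize,regions,keep_components passed to [run_session()]
#' @param included_only simulate only the sessions that enter group
#'   summaries (for the chemogenetic design: the CNO-on days). Sessions
#'   are seeded per (group, mouse, day), so the included sessions are
#'   identical whether or not the excluded days are simulated; skipping
#'   them speeds up large replicate sweeps.
#' @return an object of class `bci_experiment`: list with `design`,
#'   `sessions` (list of `session_log`), and `meta` (data.frame with one
#'   row per session: group, mouse_id, day, mode, cno_on)
#' @export
run_experiment <- function(design, agent = agent_params(),
                           profiles = default_region_profiles(),
                           config = task_config(), n_mice = NULL,
                           days = NULL, seed = 1, strength = 1,
                           synthesize = FALSE, regions = "M1",
                           keep_components = FALSE, included_only = FALSE) {
  if (!design %in% EXPERIMENT_DESIGNS) {
    stop("unknown design: ", design, " (must be one of ",
         paste(EXPERIMENT_DESIGNS, collapse = ", "), ")", call. = FALSE)
  }
  if (design == "chemogenetic") {
    groups <- c(control = "control", hM4D = "hM4D", hM3D = "hM3D")
    if (is.null(n_mice)) n_mice <- c(control = 6L, hM4D = 6L, hM3D = 6L)
    if (is.null(days)) days <- 6L
    cno_days <- seq(2, days, by = 2)
  } else if (design %in% c("optogenetic_feedback", "optogenetic_cue",
                           "optogenetic_reward")) {
    opto_mode <- switch(design,
      optogenetic_feedback = "eNpHR_at_feedback",
      optogenetic_cue = "eNpHR_at_cue",
      optogenetic_reward = "eNpHR_at_reward"
    )
    groups <- c(control = "control", eNpHR = opto_mode)
    if (is.null(n_mice)) n_mice <- c(control = 6L, eNpHR = 7L)
    if (is.null(days)) days <- 3L
    cno_days <- integer(0)
  } else if (design == "random_reward") {
    groups <- c(random_reward = "control")
    if (is.null(n_mice)) n_mice <- c(random_reward = 6L)
    if (is.null(days)) days <- 1L
    cno_days <- integer(0)
  } else { # withdrawal
    groups <- c(GO = "control", GO_no_cue = "control",
                GO_no_feedback = "control", GO_no_reward = "control")
    if (is.null(n_mice)) {
      n_mice <- stats::setNames(rep(6L, length(groups)), names(groups))
    }
    if (is.null(days)) days <- 1L
    cno_days <- integer(0)
  }
  if (is.null(names(n_mice)) || !all(names(groups) %in% names(n_mice))) {
    stop("`n_mice` must be a named vector covering the design's groups: ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  }

  sessions <- list()
  meta <- list()
  idx <- 0L
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    gmode_name <- groups[[gi]]
    for (mi in seq_len(n_mice[[gname]])) {
      mouse_id <- sprintf("%s_%02d", gname, mi)
      for (d in seq_len(days)) {
        cno_on <- if (design == "chemogenetic") d %in% cno_days else NA
        if (included_only && design == "chemogenetic" && !isTRUE(cno_on)) next
        active <- gmode_name != "control" &&
          (design != "chemogenetic" || isTRUE(cno_on))
        smode <- if (active) {
          manipulation_mode(gmode_name, strength = strength)
        } else {
          manipulation_mode("control")
        }
        variant <- switch(design,
          random_reward = "random_reward",
          withdrawal = gname,
          NULL
        )
        sseed <- derive_seed(seed, gi * 1000003, mi * 10007, d)
        log <- run_session(agent, profiles, config, mode = smode,
                           seed = sseed, mouse_id = mouse_id, day = d,
                           synthesize = synthesize, regions = regions,
                           trial_variant = variant,
                           keep_components = keep_components)
        log$cno_on <- cno_on
        idx <- idx + 1L
        sessions[[idx]] <- log
        meta[[idx]] <- data.frame(
          group = gname, mouse_id = mouse_id, day = d,
          mode = smode$mode, cno_on = cno_on, session = idx,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(design = design, sessions = sessions, meta = do.call(rbind, meta),
         seed = seed),
    class = "bci_experiment"
  )
}

#' @export
print.bci_experiment <- function(x, ...) {
  cat(sprintf("<bci_experiment> design %s: %d sessions\n",
              x$design, length(x$sessions)))
  tab <- table(x$meta$group)
  cat("  groups: ",
      paste(sprintf("%s (%d sessions)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sessions included in group summaries for an experiment
#'
#' Chemogenetic designs include only the CNO-on days (the three alternate
#' administration days); all other designs include every session.
#'
#' @param experiment a `bci_experiment`
#' @return integer vector of session indices
#' @export
included_sessions <- function(experiment) {
  m <- experiment$meta
  if (experiment$design == "chemogenetic") {
    m$session[m$cno_on %in% TRUE]
  } else {
    m$session
  }
}
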
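#' Simulate from a run configuration and write logs to disk
#'
#' The simulation entry point behind the command-line wrapper: validates
#' the configuration, runs a single session (no `design`) or a full
#' experiment, writes every session with [write_session()], and prints a
#' short summary.
#'
#' @param config a run-config list or a path to a YAML file
#'   (see [default_run_config()])
#' @param out_dir output directory
#' @param quiet suppress the printed summary
#' @return (invisibly) the simulated `session_log` or `bci_experiment`
#' @export
simulate_run <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  inst <- instantiate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(inst$design)) {
    res <- run_session(inst$agent, inst$profiles, inst$config,
                       mode = inst$mode, seed = inst$seed,
                       synthesize = inst$synthesize, regions = inst$regions)
    write_session(res, out_dir)
    if (!quiet) print(res)
  } else {
    res <- run_experiment(inst$design, agent = inst$agent,
                          profiles = inst$profiles, config = inst$config,
                          n_mice = inst$n_mice, days = inst$days,
                          seed = inst$seed,
                          strength = config$strength %||% 1,
                          synthesize = inst$synthesize,
                          regions = inst$regions)
    for (i in seq_along(res$sessions)) {
      g <- res$meta$group[i]
      log <- res$sessions[[i]]
      write_session(log, file.path(out_dir, g))
    }
    if (!quiet) print(res)
  }
  # provenance: the generating config travels with the data
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(res)
}

#' Analyze a directory of simulated session logs
#'
#' Reads every session under `log_dir` (optionally nested one level by
#' group), computes the behavioral endpoint table and, when traces are
#' present, the component peak table, and writes `results.csv`,
#' `peaks.csv` and `results.json` to `out_dir`. When the logs contain a
#' control group plus at least one other group, each endpoint is also
#' compared between groups (test, statistic, p-value, stars).
#'
#' @param log_dir directory produced by [simulate_run()]
#' @param out_dir output directory (default `log_dir`)
#' @param endpoints behavioral endpoints to tabulate
#' @param quiet suppress the printed report
#' @return (invisibly) list with `sessions`, `behavior`, `peaks`,
#'   `comparisons`
#' @export
analyze_run <- function(log_dir, out_dir = log_dir,
                        endpoints = c("go_success", "nogo_success", "go_rt",
                                      "nogo_error_rt", "total_licks"),
                        quiet = FALSE) {
  if (!dir.exists(log_dir)) {
    stop("log directory does not exist: ", log_dir, call. = FALSE)
  }
  dirs <- c(log_dir, list.dirs(log_dir, recursive = FALSE))
  sessions <- list()
  meta <- list()
  for (d in dirs) {
    for (stem in list_sessions(d)) {
      log <- read_session(d, stem)
      sessions[[length(sessions) + 1]] <- log
      grp <- if (identical(normalizePath(d), normalizePath(log_dir))) {
        sub("_[0-9]+$", "", log$mouse_id)
      } else {
        basename(d)
      }
      meta[[length(sessions)]] <- data.frame(
        group = grp, mouse_id = log$mouse_id, day = log$day,
        mode = log$mode, cno_on = log$cno_on,
        session = length(sessions), stringsAsFactors = FALSE
      )
    }
  }
  if (length(sessions) == 0) {
    stop("no session logs found under ", log_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  behavior <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    log <- sessions[[i]]
    vals <- vapply(endpoints, function(e) {
      tryCatch(session_endpoint(log, e), error = function(err) NA_real_)
    }, numeric(1))
    cbind(meta[[i]][c("group", "mouse_id", "day", "mode")],
          as.data.frame(as.list(vals)))
  }))
  utils::write.csv(behavior, file.path(out_dir, "results.csv"),
                   row.names = FALSE)

  peaks <- do.call(rbind, lapply(sessions, function(log) {
    pk <- peak_table(log)
    if (is.null(pk)) NULL else pk
  }))
  if (!is.null(peaks)) {
    utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  }

  # group comparisons when a control group is present
  comparisons <- NULL
  groups <- unique(vapply(meta, function(m) m$group, character(1)))
  if (length(groups) >= 2 && "control" %in% groups) {
    cno <- vapply(meta, function(m) isTRUE(m$cno_on), logical(1))
    design <- if (any(cno)) "chemogenetic" else "custom"
    exp_obj <- structure(
      list(design = design, sessions = sessions, meta = do.call(rbind, meta)),
      class = "bci_experiment"
    )
    comparisons <- do.call(rbind, lapply(endpoints, function(e) {
      tryCatch(summarize_and_compare(exp_obj, e, test = "both"),
               error = function(err) NULL)
    }))
  }

  report <- list(
    schema_version = SCHEMA_VERSION,
    n_sessions = length(sessions),
    groups = groups,
    endpoints = endpoints,
    comparisons = comparisons
  )
  jsonlite::write_json(report, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (!quiet) {
    cat(sprintf("analyzed %d sessions (%s)\n", length(sessions),
                paste(groups, collapse = ", ")))
    if (!is.null(comparisons)) print(comparisons)
  }
  invisible(list(sessions = sessions, behavior = behavior, peaks = peaks,
                 comparisons = comparisons))
}

#' Build seeded fixture datasets
#'
#' Writes small, fully seeded datasets used by examples and tests:
#' `smoke` builds one short traced session plus a behavior-only mini
#' experiment; `full` builds the two group designs at their study sizes
#' (chemogenetic 6/6/6 over 6 days, optogenetic 6/7) at reduced trial
#' counts, behavior-only. Every fixture directory carries its generating
#' configuration.
#'
#' @param scale `"smoke"` or `"full"`
#' @param out_dir output directory
#' @param seed integer seed
#' @return (invisibly) character vector of fixture directories
#' @export
make_fixtures <- function(scale = c("smoke", "full"), out_dir, seed = 1) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(0)
  if (scale == "smoke") {
    cfg <- default_run_config(seed = seed)
    cfg$task$n_success_target <- 5
    cfg$task$max_trials <- 30
    d1 <- file.path(out_dir, "single_session")
    simulate_run(cfg, d1, quiet = TRUE)
    cfg2 <- default_run_config(design = "withdrawal", seed = seed + 1,
                               synthesize = FALSE, regions = "M1")
    cfg2$task$n_success_target <- 5
    cfg2$task$max_trials <- 30
    cfg2$n_mice <- list(GO = 2, GO_no_cue = 2, GO_no_feedback = 2,
                        GO_no_reward = 2)
    d2 <- file.path(out_dir, "withdrawal_mini")
    simulate_run(cfg2, d2, quiet = TRUE)
    dirs <- c(d1, d2)
  } else {
    cfg <- default_run_config(design = "chemogenetic", seed = seed,
                              synthesize = FALSE, regions = "M1")
    cfg$task$n_success_target <- 15
    cfg$task$max_trials <- 60
    d1 <- file.path(out_dir, "chemogenetic")
    simulate_run(cfg, d1, quiet = TRUE)
    cfg2 <- default_run_config(design = "optogenetic_feedback",
                               seed = seed + 1, synthesize = FALSE,
                               regions = "M1")
    cfg2$task$n_success_target <- 15
    cfg2$task$max_trials <- 60
    d2 <- file.path(out_dir, "optogenetic_feedback")
    simulate_run(cfg2, d2, quiet = TRUE)
    dirs <- c(d1, d2)
  }
  invisible(dirs)
}
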
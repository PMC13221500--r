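#' Write one session to disk
#'
#' Emits the session's flat event table (CSV), the concatenated region
#' traces (CSV, one time column in seconds plus one column per region,
#' absolute session time), and a JSON sidecar carrying the schema
#' version, the seed, the configuration snapshot and summary counts.
#'
#' @param log a `session_log`
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_session <- function(log, dir) {
  stopifnot(inherits(log, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_d%02d", log$mouse_id, log$day)
  paths <- c(events = file.path(dir, paste0("events_", stem, ".csv")),
             sidecar = file.path(dir, paste0("session_", stem, ".json")))
  ev <- session_events(log)
  utils::write.csv(ev, paths[["events"]], row.names = FALSE)

  has_traces <- any(vapply(log$trials, function(tr) !is.null(tr$traces),
                           logical(1)))
  if (has_traces) {
    paths[["traces"]] <- file.path(dir, paste0("traces_", stem, ".csv"))
    pieces <- lapply(seq_along(log$trials), function(i) {
      tr <- log$trials[[i]]
      if (is.null(tr$traces)) return(NULL)
      df <- data.frame(time_s = tr$traces[[1]]$times + log$trial_onsets[i])
      for (rg in names(tr$traces)) df[[rg]] <- tr$traces[[rg]]$values
      df
    })
    all_tr <- do.call(rbind, pieces)
    # adjacent trial windows share their boundary sample; keep one copy
    all_tr <- all_tr[!duplicated(round(all_tr$time_s * 1e6)), , drop = FALSE]
    utils::write.csv(all_tr, paths[["traces"]], row.names = FALSE)
  }

  side <- list(
    schema_version = SCHEMA_VERSION,
    mouse_id = log$mouse_id,
    day = log$day,
    mode = log$mode,
    cno_on = log$cno_on,
    seed = log$seed,
    rate = log$config$rate,
    pre_baseline_s = log$config$pre_baseline_s,
    n_presented = log$n_presented,
    n_success = log$n_success,
    capped = log$capped,
    duration_s = log$duration_s,
    trial_onsets = log$trial_onsets,
    config = unclass(log$config)
  )
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a session written by [write_session()]
#'
#' Rebuilds a `session_log` (trial records, licks, and per-trial trace
#' slices when a trace file is present) from the CSV/JSON trio. Sidecars
#' with an unknown schema version are rejected.
#'
#' @param dir directory containing the files
#' @param stem session stem, e.g. `"m1_d01"`
#' @return a `session_log`
#' @export
read_session <- function(dir, stem) {
  side_path <- file.path(dir, paste0("session_", stem, ".json"))
  ev_path <- file.path(dir, paste0("events_", stem, ".csv"))
  if (!file.exists(side_path) || !file.exists(ev_path)) {
    stop("no session files for stem ", stem, " in ", dir, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(as.character(side$schema_version), SCHEMA_VERSION)) {
    stop("unsupported session schema version: ", side$schema_version,
         call. = FALSE)
  }
  ev <- utils::read.csv(ev_path, stringsAsFactors = FALSE)
  tc <- side$config
  tc$threshold_rule <- as.list(tc$threshold_rule)
  config <- do.call(task_config, tc)

  tr_path <- file.path(dir, paste0("traces_", stem, ".csv"))
  traces_df <- if (file.exists(tr_path)) {
    utils::read.csv(tr_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }

  onsets <- side$trial_onsets
  trial_idx <- sort(unique(ev$trial_index[!is.na(ev$trial_index)]))
  trials <- lapply(trial_idx, function(ti) {
    rows <- ev[!is.na(ev$trial_index) & ev$trial_index == ti, , drop = FALSE]
    onset <- onsets[ti]
    traces <- NULL
    if (!is.null(traces_df)) {
      conclude <- rows$time_s[rows$event_class == "iti_start"][1]
      sel <- traces_df$time_s >= onset - config$pre_baseline_s - 1e-9 &
        traces_df$time_s <= onset + conclude + config$post_s + 1e-9
      if (any(sel)) {
        sub <- traces_df[sel, , drop = FALSE]
        sub <- sub[!duplicated(round(sub$time_s * 1e6)), , drop = FALSE]
        regions <- setdiff(names(sub), "time_s")
        traces <- lapply(regions, function(rg) {
          bci_trace(round((sub$time_s - onset) * config$rate) / config$rate,
                    sub[[rg]], rate = config$rate, region = rg, units = "au")
        })
        names(traces) <- regions
      }
    }
    trial_result(
      trial_index = ti,
      trial_type = rows$trial_type[1],
      outcome = rows$outcome[1],
      events = data.frame(event_class = rows$event_class,
                          time_s = rows$time_s),
      response_time = rows$response_time_s[1],
      threshold_used = rows$threshold[1],
      conclude_s = rows$time_s[rows$event_class == "iti_start"][1],
      traces = traces
    )
  })

  structure(
    list(
      mouse_id = side$mouse_id, day = side$day, mode = side$mode,
      cno_on = if (is.null(side$cno_on)) NA else side$cno_on,
      config = config, seed = side$seed,
      trials = trials, trial_onsets = onsets,
      licks = ev$abs_time_s[ev$event_class == "lick"],
      reward_times = sort(ev$abs_time_s[ev$event_class == "reward"]),
      duration_s = side$duration_s,
      n_presented = side$n_presented, n_success = side$n_success,
      capped = side$capped
    ),
    class = "session_log"
  )
}

#' List session stems in a log directory
#' @param dir directory of files written by [write_session()]
#' @return character vector of stems
#' @export
list_sessions <- function(dir) {
  f <- list.files(dir, pattern = "^session_.*\\.json$")
  sub("^session_(.*)\\.json$", "\\1", f)
}
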
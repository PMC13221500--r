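#' Schema version of serialized outputs
#' @keywords internal
SCHEMA_VERSION <- "1.0"

#' Default run configuration
#'
#' A single structured document collecting every simulation parameter:
#' task constants, agent parameters, region profiles, manipulation mode,
#' experiment design, and seeds. Round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param design `NULL` for a single session, or an experiment design name
#'   (see [run_experiment()])
#' @param seed integer seed
#' @param synthesize synthesise traces
#' @param regions regions to synthesise
#' @return a named list (class `run_config`)
#' @export
default_run_config <- function(design = NULL, seed = 1, synthesize = TRUE,
                               regions = c("M1", "GPe", "STN")) {
  structure(
    list(
      version = SCHEMA_VERSION,
      design = design,
      seed = seed,
      synthesize = synthesize,
      regions = regions,
      mode = "control",
      strength = 1,
      days = NULL,
      n_mice = NULL,
      task = unclass(task_config()),
      agent = unclass(agent_params()),
      profiles = serialize_profiles(default_region_profiles())
    ),
    class = "run_config"
  )
}

serialize_profiles <- function(profiles) {
  lapply(profiles, function(p) {
    list(
      baseline_F = p$baseline_F,
      noise_sd = p$noise_sd,
      kernels = lapply(p$kernels, function(k) {
        list(amplitude = k$amplitude, rise_tau = k$rise_tau,
             decay_tau = k$decay_tau)
      })
    )
  })
}

deserialize_profiles <- function(x) {
  out <- lapply(names(x), function(rg) {
    p <- x[[rg]]
    region_profile(rg, p$baseline_F, p$noise_sd,
                   lapply(p$kernels, function(k) {
                     transient_kernel(k$amplitude, k$rise_tau, k$decay_tau)
                   }))
  })
  stats::setNames(out, names(x))
}

RUN_CONFIG_KEYS <- c("version", "design", "seed", "synthesize", "regions",
                     "mode", "strength", "days", "n_mice", "task", "agent",
                     "profiles")

#' Validate a run configuration
#'
#' Rejects unknown keys and re-validates the task, agent and profile
#' blocks through their constructors.
#'
#' @param cfg a run-config list
#' @return the validated config (class `run_config`), invisibly usable
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_k <- setdiff(c("version", "seed", "task", "agent", "profiles"),
                       names(cfg))
  if (length(missing_k) > 0) {
    stop("run config is missing keys: ", paste(missing_k, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(cfg$version), SCHEMA_VERSION)) {
    stop("unsupported run-config version: ", cfg$version,
         " (this package reads version ", SCHEMA_VERSION, ")", call. = FALSE)
  }
  # constructors re-check every field
  do.call(task_config, cfg$task)
  do.call(agent_params, cfg$agent)
  deserialize_profiles(cfg$profiles)
  as_manipulation_mode(cfg$mode)
  if (!is.null(cfg$design) && !cfg$design %in% EXPERIMENT_DESIGNS) {
    stop("unknown design in run config: ", cfg$design, call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#' @param cfg a run-config list
#' @param path output file path
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(unclass(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read and validate a run configuration from YAML
#' @param path YAML file written by [write_run_config()] (or hand-edited)
#' @return validated config (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  # YAML reads numeric vectors back as lists in some layouts; normalise
  if (!is.null(cfg$regions)) cfg$regions <- unlist(cfg$regions)
  validate_run_config(cfg)
}

# Materialise R objects from a validated config
instantiate_run_config <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  tc <- cfg$task
  tc$threshold_rule <- lapply(tc$threshold_rule, identity)
  list(
    config = do.call(task_config, tc),
    agent = do.call(agent_params, cfg$agent),
    profiles = deserialize_profiles(cfg$profiles),
    mode = manipulation_mode(cfg$mode, strength = cfg$strength %||% 1),
    design = cfg$design,
    seed = cfg$seed,
    synthesize = isTRUE(cfg$synthesize),
    regions = cfg$regions,
    days = cfg$days,
    n_mice = if (is.null(cfg$n_mice)) NULL else unlist(cfg$n_mice)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
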
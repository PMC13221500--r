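# Independent oracles used to freeze expected values. These deliberately
# use brute-force formulations, not the package's code paths.

# Exhaustive window-mean oracle for the moving-average filter.
oracle_moving_average <- function(times, values, span_ms, step_ms) {
  half <- span_ms / 2000
  out_t <- seq(times[1], times[length(times)], by = step_ms / 1000)
  out_v <- vapply(out_t, function(tt) {
    mean(values[times >= tt - half - 1e-9 & times <= tt + half + 1e-9])
  }, numeric(1))
  list(times = out_t, values = out_v)
}

# Closed-form pooled-variance Student's t.
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(statistic = t, p_value = p)
}

# Exact two-tailed Mann-Whitney p by full enumeration of all
# choose(na+nb, na) group assignments (no ties assumed).
oracle_mw_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    ua <- sum(outer(x, y, ">")) # no ties
    min(ua, na * nb - ua)
  }
  u_obs <- u_stat(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_stat)
  list(U = u_obs, p_value = mean(us <= u_obs))
}

# Small, fast task configuration for behavioral tests.
fast_config <- function(...) {
  args <- list(n_success_target = 10, max_trials = 60)
  over <- list(...)
  args[names(over)] <- over
  do.call(task_config, args)
}

# Deterministic agent: always succeeds / always inhibits.
perfect_agent <- function(...) {
  agent_params(p_go_success = 1, p_inhibit = 1, premature_rate = 0, ...)
}

# Noise-free region profiles.
quiet_profiles <- function() {
  default_region_profiles(noise_sd = 0)
}
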
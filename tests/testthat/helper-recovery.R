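# Significance-pattern checks used by the recovery suite. A contrast is
# "significant" under the concordance rule (Student's t and Mann-Whitney
# both below 0.05, see summarize_and_compare(test = "both")).

row_for <- function(df, grp) df[df$group == grp, , drop = FALSE]

# hM3D: GO down, NO-GO up, licks down, GO RT unchanged.
# hM4D: GO / NO-GO / licks / RT unchanged.
check_chemo_patterns <- function(seed) {
  ex <- run_experiment("chemogenetic", seed = seed, included_only = TRUE)
  go <- summarize_and_compare(ex, "go_success", test = "both")
  ng <- summarize_and_compare(ex, "nogo_success", test = "both")
  lk <- summarize_and_compare(ex, "total_licks", test = "both")
  rt <- summarize_and_compare(ex, "go_rt", test = "both")
  h3 <- list(go = row_for(go, "hM3D"), ng = row_for(ng, "hM3D"),
             lk = row_for(lk, "hM3D"), rt = row_for(rt, "hM3D"))
  h4 <- list(go = row_for(go, "hM4D"), ng = row_for(ng, "hM4D"),
             lk = row_for(lk, "hM4D"), rt = row_for(rt, "hM4D"))
  c(
    hM3D = h3$go$significant && h3$go$mean_group < h3$go$mean_control &&
      h3$ng$significant && h3$ng$mean_group > h3$ng$mean_control &&
      h3$lk$significant && h3$lk$mean_group < h3$lk$mean_control &&
      !h3$rt$significant,
    hM4D = !h4$go$significant && !h4$ng$significant &&
      !h4$lk$significant && !h4$rt$significant
  )
}

# eNpHR at feedback: GO down, GO RT up, NO-GO up, licks unchanged.
# eNpHR at cue / reward: all behavioral endpoints unchanged.
check_opto_pattern <- function(design, seed, expect_effect) {
  ex <- run_experiment(design, seed = seed)
  go <- summarize_and_compare(ex, "go_success", test = "both")
  ng <- summarize_and_compare(ex, "nogo_success", test = "both")
  rt <- summarize_and_compare(ex, "go_rt", test = "both")
  lk <- summarize_and_compare(ex, "total_licks", test = "both")
  if (expect_effect) {
    go$significant && go$mean_group < go$mean_control &&
      ng$significant && ng$mean_group > ng$mean_control &&
      rt$significant && rt$mean_group > rt$mean_control &&
      !lk$significant
  } else {
    !go$significant && !ng$significant && !rt$significant && !lk$significant
  }
}
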
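# stopbci

Closed-loop simulation and analysis of a volitional stop-signal (GO/NO-GO)
brain–computer interface paradigm.

## The problem

In the paradigm this package models, a head-fixed mouse volitionally
controls the bulk calcium signal of its own motor cortex (M1), recorded
through a fiber-photometry system, against a threshold. A 5,000-Hz GO cue
opens a 30-s window in which the animal must drive ΔF/F = (F − F₀)/F₀
above the threshold; the crossing triggers a 10,000-Hz auditory feedback
tone (500 ms) and a sucrose reward 1 s after feedback onset. On NO-GO
trials a 27,000-Hz stop cue sounds 2 s after the GO cue, and the animal
must instead hold the signal below threshold for 13 s. Trials mix
67% GO / 33% NO-GO at random, a session runs to 50 successes, and
chemogenetic (hM3D/hM4D + CNO) or time-locked optogenetic (eNpHR)
manipulations of the M2→GPe projection shift task performance and the
event-locked calcium transients.

No public data accompany the paradigm, so the package pairs each analysis
stage with a generator whose ground truth is known:

* **synthetic neural data** — multi-region calcium traces as baseline +
  Gaussian noise + event-locked difference-of-exponential transients
  (amplitude *a*·(e^(−t/τ_d) − e^(−t/τ_r)), peak-normalised), lick
  trains, and a parametric behavioral agent;
* **task engine** — the closed-loop GO/NO-GO state machine with
  withdrawal variants (no cue / no feedback / no reward), a random-reward
  control, stochastic scheduling, session termination, and the multi-day
  group designs (6/6/6 chemogenetic over 6 days with CNO on alternate
  days; 6 vs 7 optogenetic);
* **photometry** — moving-average smoothing (20-ms span, 10-ms step),
  cue-locked ΔF/F conversion, peri-event alignment (reward at time 0,
  −15/+10 s), and per-component peak extraction in event-anchored
  windows;
* **behavior statistics** — per-type success rates, response times
  (trial onset → threshold crossing), lick totals, the 85–100%
  three-consecutive-day training criterion, per-mouse session averaging,
  pooled-variance Student's t and exact/corrected Mann–Whitney U tests
  with 0.05/0.01/0.001 stars.

See `vignettes/stop-signal-bci.Rmd` for the model, parameter defaults,
and design decisions.

## A worked example

```r
library(stopbci)

agent    <- agent_params()              # a trained mouse (88% GO, 88% inhibit)
profiles <- default_region_profiles()   # M1, GPe, STN response profiles
log <- run_session(agent, profiles, task_config(), seed = 1,
                   synthesize = TRUE, regions = c("M1", "GPe", "STN"))
log
#> <session_log> mouse m1 day 1 (control)
#>   54 trials presented, 50 successes; 1063 s; 625 licks
#>   GO: success rate 0.95 (39 presented)
#>   NOGO: success rate 0.87 (15 presented)
```

The session terminated after 50 successes; 39 GO and 15 NO-GO trials were
presented (close to the 67/33 mix), and the agent's measured success
rates (0.95, 0.87) scatter around its programmed probabilities. The
photometry pipeline then recovers per-trial component peaks from the
synthesised traces:

```r
head(peak_table(log))
#>  trial_index trial_type region  component  peak_dff
#>            1         GO     M1     go_cue 0.2489858
#>            1         GO     M1   feedback 1.2397771
#>            1         GO     M1     reward 1.2767088
#>            1         GO     M1 volitional 0.5494937
```

The cue peak (≈0.25 ΔF/F) matches the generator amplitude (0.3) within
noise; the feedback/reward windows measure composite amplitudes because
the slow volitional transient is still decaying inside them — the same
superposition present in real recordings, and the reason the withdrawal
variants exist (see the vignette).

A full group design, summarised one point per mouse over the three CNO-on
days and tested against control:

```r
ex <- run_experiment("chemogenetic", seed = 1, included_only = TRUE)
summarize_and_compare(ex, "go_success", test = "both")
#>    endpoint group mean_control mean_group          p_t         p_u stars significant
#>  go_success  hM3D    0.8759906  0.5175386 5.869721e-08 0.002164502    **        TRUE
#>  go_success  hM4D    0.8759906  0.8786047 9.098433e-01 0.818181818            FALSE
```

Activating the M2-innervated GPe population (hM3D) collapses GO success
(0.88 → 0.52, significant under both tests); inhibiting it (hM4D) leaves
GO performance untouched — the programmed effect directions recovered by
the analysis.

Simulation and analysis also run from the shell via the thin wrapper in
`inst/scripts/stopbci` (`simulate`, `analyze`, `fixtures`, `config`
subcommands over YAML run configurations).

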
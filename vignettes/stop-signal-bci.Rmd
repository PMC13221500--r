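---
title: "Simulating and analysing the volitional stop-signal BCI task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the volitional stop-signal BCI task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopbci)
```

## The paradigm

In the volitional stop-signal task a head-fixed mouse controls the bulk
calcium signal of its own primary motor cortex (M1), recorded by fiber
photometry, against a threshold. On a **GO** trial a 5,000-Hz cue opens a
30-s window in which the animal must drive ΔF/F above the threshold; the
crossing triggers a 10,000-Hz feedback tone (500 ms) and, 1 s after
feedback onset, a sucrose reward. On a **NO-GO** trial a 27,000-Hz stop
cue sounds 2 s after the GO cue and the animal must instead hold the
signal *below* threshold for 13 s; a completed hold earns the same
feedback-then-reward sequence. Trials are drawn at random with a 67/33
GO/NO-GO mix, separated by a 10-s inter-trial interval, and a session
ends after 50 successful trials. Success rates are computed per trial
type (successes over presented trials of that type), and the response
time is the interval from trial onset to the threshold crossing.

`stopbci` implements this closed loop in full — a parametric mouse agent,
a trace generator, and the task state machine — together with the
downstream photometry and behavioral analyses, so that every analysis
stage can be exercised against data whose ground truth is known.

## The synthetic calcium signal

Each region (M1, and the basal-ganglia nuclei GPe and STN innervated by
the premotor cortex M2) is a `region_profile`: a constant baseline
(1 a.u., so amplitudes read directly as ΔF/F), i.i.d. Gaussian noise
(default SD 0.02 ΔF/F), and one transient kernel per event class —
GO cue, stop cue, feedback, reward, and the volitional ramp. Kernels are
peak-normalised differences of exponentials,
$a\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, the standard phenomenological shape
of a GCaMP-style indicator transient. Brief tone-evoked responses (cues,
feedback) use $\tau_r = 0.05$ s, $\tau_d = 0.4$ s; the slower reward and
volitional components use $\tau_d = 1$ s. The paradigm defines the
component structure only qualitatively (arrow-marked peaks on
representative traces), so all
amplitudes are free parameters; the defaults (e.g. M1: cue 0.3, feedback
0.5, reward 0.8, volitional 0.9 ΔF/F) were chosen once for clear
component separation and are not calibrated to any recording.

The generator returns the per-class components alongside the composite
trace, which makes two properties testable exactly: *additivity*
(baseline + noise + summed components reconstruct the trace bit for bit)
and *ablation* (withholding an event removes exactly its component).
There is no photobleaching drift, motion artefact or isosbestic channel
— none of these are part of the modelled recordings — and no spiking or
biophysics: the model operates at the level the analysis consumes.

## The closed loop and the agent

The control signal is ΔF/F computed online with a cue-locked baseline
(below), monitored on the 100-Hz simulation grid; the trigger is the
first sample at or above threshold, so a one-sample decision latency is
inherent. The agent is behavioral, not biophysical: it succeeds on a GO
trial with probability `p_go_success`, starting its volitional ramp a
Gaussian latency after the cue and crossing `ramp_duration` seconds
later; on NO-GO trials it withholds with probability `p_inhibit` and
crosses prematurely (before the stop cue) with probability
`premature_rate` — premature crossings are scored as failed NO-GO trials
with a response time, and flagged, since the published scoring for this
edge case is not stated. Defaults (`p_go_success = 0.88`,
`p_inhibit = 0.88`, `premature_rate = 0.03`) describe an animal that has
passed the training criterion of 85–100% correct over three consecutive
days on both trial types; latency defaults (4 ± 1.5 s, 2-s ramp) give
response times well inside the 30-s window. Licking is a homogeneous
Poisson bout (6 licks/s for 2 s) after each reward.

Two design choices deserve explanation:

* **Threshold rule.** The published task used "a defined threshold
  value" without stating it. The package defaults to a *fixed* 0.5 ΔF/F.
  An adaptive rule (pre-cue baseline mean + k·SD) is also implemented,
  but it is not the default: under a first-sample trigger, a
  noise-quantile threshold lies below both the cue-evoked transient
  (≈0.3 ΔF/F) and the expected extreme of the ~3×10³ baseline samples in
  a 30-s window, so it would fire spuriously on essentially every trial.
  A fixed threshold above the cue response and far above the noise floor
  (25 SD) reflects how such neurofeedback thresholds are set in practice.
* **Closed-loop trace generation.** Trials are resolved in two passes
  over a shared seeded noise stream: the pre-crossing signal is
  synthesised, the crossing detected on it, and the full trace then
  regenerated with the feedback/reward events appended. Because kernels
  vanish at onset, appended events cannot perturb the already-detected
  crossing, so the loop is exactly consistent. For purely behavioral
  endpoints `synthesize = FALSE` computes the same crossing from the
  noiseless volitional component on the same grid — with the default
  threshold 25 noise SDs above baseline the two paths agree, and the
  fast path makes thousand-replicate calibration sweeps practical.

## Manipulation models

`manipulation_mode()` encodes the circuit manipulations as multiplicative
effects whose *directions* follow the reported contrasts and whose
magnitudes are free defaults: chemogenetic activation of M2-innervated
GPe neurons (hM3D, CNO-activated) lowers `p_go_success` (×0.6), raises
`p_inhibit` (×1.4, capped at 1), lowers licking (×0.7) and halves the GPe
feedback transient; inhibition (hM4D) leaves behavior untouched but
suppresses the M1 reward and STN/GPe feedback transients; time-locked
optogenetic inhibition (eNpHR) applies its signal suppression only inside
a 1-s window locked to the targeted event — feedback-locked inhibition
also shifts behavior (GO success ×0.7, GO latency ×1.3, `p_inhibit`
×1.3), while cue- and reward-locked inhibition leave behavior unchanged.
A `strength` exponent scales every factor continuously, which the test
suite uses to check that, e.g., GO success falls monotonically with hM3D
strength under common random numbers.

The chemogenetic design runs six days with CNO on alternate days; only
the three CNO-on sessions enter group summaries, mirroring the averaging
that yields one independent point per mouse. Group sizes default to the
published designs (6/6/6; control 6 vs eNpHR 7). Optogenetic designs run
three sessions per mouse.

## Photometry processing

Processing follows the published pipeline: a centred moving-average
filter (20-ms span, 10-ms step; edge windows truncated, never padded, so
constants are preserved), then ΔF/F = (F − F₀)/F₀ with F₀ the mean
fluorescence in the 10 ms at the auditory cue — read here as the 10 ms
*following* cue onset, one of two defensible readings of "within 10 ms
of", and the one that needs no pre-cue samples. Segments are aligned to
reward delivery (time 0) with 15 s before / 10 s after by default (10/10
in the optogenetic analyses).

Component peaks are the maxima of ΔF/F inside windows anchored at each
component's own logged event: cues and feedback [0, +1] s from onset,
reward [0, +3] s, and the volitional signal [−2, 0] s before the
threshold crossing — it has no event of its own, being the build-up that
attains the threshold. The paradigm identifies its components only
qualitatively (arrow-marked peaks on representative traces), so these
numeric windows are package defaults, all configurable.
When the feedback tone is withheld (withdrawal variant) its window is
anchored at the crossing, where the tone would have sounded, so the
residual signal remains measurable.

One caveat is inherent and worth stating plainly: with a ~1-s indicator
decay, components that are close in time overlap, so a windowed peak
measures the local composite amplitude, not an isolated component — on GO
trials the volitional surge is still decaying inside the feedback window.
This mirrors the real recordings (it is why the withdrawal experiments
exist), and it is why the identifiability test compares the measured peak
against the *noiseless composite* windowed maximum (agreement within 10%
for ≥95% of trials), while component-level claims are tested on the
generator's exact per-class decomposition. Group contrasts are unaffected
because the overlapping contribution is common to both groups.

## Statistics

Endpoints are summarised per mouse (sessions averaged under the design's
inclusion rule) and compared between groups with an unpaired two-tailed
pooled-variance Student's t test and a two-tailed Mann–Whitney U test
(exact by enumeration for combined n ≤ 16 without ties, tie-corrected
normal approximation otherwise; U is reported as min(U₁, U₂)). Stars
follow the 0.05/0.01/0.001 convention; no multiple-testing correction is
applied, matching per-comparison reporting. Because the source does not
state which endpoints used which test ("as appropriate"), the package's
convention is: Mann–Whitney for bounded success-rate endpoints, Student's
t for continuous ones (times, lick counts, peaks); `test = "both"` runs
both and calls a contrast significant only when the two agree at α =
0.05, the rule used by the recovery suite so that disagreements between
the tests are resolved conservatively rather than silently.

Degenerate inputs are handled explicitly: two constant equal samples give
t = 0, p = 1; constant unequal samples are flagged rather than producing
an infinite statistic silently; ties switch the U test to its corrected
approximation.

## What the tests do and do not show

The simulation reproduces the paradigm's *structure* (timing, trial mix,
closed-loop contingency, group designs) and the analysis pipeline's
*behavior on known ground truth*. The acceptance suite verifies: exact
event timing read from logs; scheduler convergence to the 67% GO mix and
termination at 50 successes; equivalence of the smoothing and the
two-group tests with brute-force oracles; ΔF/F identities (zero on
constants, invariance under positive rescaling of F, closed-form F₀);
exact single-component ablation under withdrawal plus its detectability
in 6-vs-6 group comparisons at default noise (≥80% of 100 replicates);
5% type-I calibration of both tests on null experiments (1000
replicates); and recovery of the qualitative significance pattern of
every manipulation in ≥80% of 100 replicates per manipulation. The
pattern criterion is evaluated per manipulation mode: with ~14 null
contrasts across the full matrix, calibrated 5% tests cannot jointly
hold all of them 80% of the time — any procedure that could would be
miscalibrated.

Replicate sweeps use reduced problem sizes chosen for desk-scale
runtimes: calibration sessions run to 25 successes, ablation replicates
use 6 GO trials per mouse, and chemogenetic sweeps simulate only the
three CNO-on sessions per mouse (sessions are seeded independently, so
the excluded days change nothing; the suite verifies this equivalence).

None of this validates claims about real animals. The generator's
amplitudes, effect magnitudes and agent parameters are free defaults,
inter-mouse variability is purely binomial/sampling (no random effects),
there is no learning within or across sessions, no drift or artefacts,
and the noise is white Gaussian. What a passing suite shows is that the
pipeline measures what it claims to measure on data with those
properties — and would therefore be trustworthy plumbing for data whose
properties are argued separately.

## A worked session

```{r example, eval = FALSE}
library(stopbci)

agent <- agent_params()
profiles <- default_region_profiles()
log <- run_session(agent, profiles, task_config(), seed = 1,
                   synthesize = TRUE, regions = c("M1", "GPe", "STN"))
log
success_rate(log, "GO")
head(peak_table(log))

ex <- run_experiment("chemogenetic", seed = 1, included_only = TRUE)
summarize_and_compare(ex, "go_success", test = "both")
```
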
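version: '1.0'
design: ~
seed: 1.0
synthesize: yes
regions:
- M1
- GPe
- STN
mode: control
strength: 1.0
days: ~
n_mice: ~
task:
  go_cue_hz: 5000.0
  stop_cue_hz: 27000.0
  feedback_hz: 10000.0
  feedback_duration: 0.5
  go_window: 30.0
  stop_delay: 2.0
  hold_duration: 13.0
  reward_delay: 1.0
  iti: 10.0
  p_go: 0.67
  n_success_target: 50.0
  max_trials: 500.0
  threshold_rule:
    type: fixed
    value: 0.5
  scheduler: bernoulli
  rate: 100.0
  pre_baseline_s: 5.0
  post_s: 5.0
agent:
  p_go_success: 0.88
  go_latency_mean: 4.0
  go_latency_sd: 1.5
  ramp_duration: 2.0
  p_inhibit: 0.88
  premature_rate: 0.03
  lick_rate: 6.0
  lick_bout_duration: 2.0
profiles:
  M1:
    baseline_F: 1.0
    noise_sd: 0.02
    kernels:
      go_cue:
        amplitude: 0.3
        rise_tau: 0.05
        decay_tau: 0.4
      stop_cue:
        amplitude: 0.0
        rise_tau: 0.05
        decay_tau: 0.4
      feedback:
        amplitude: 0.5
        rise_tau: 0.05
        decay_tau: 0.4
      reward:
        amplitude: 0.8
        rise_tau: 0.1
        decay_tau: 1.0
      volitional_ramp:
        amplitude: 0.9
        rise_tau: 0.3
        decay_tau: 1.0
  GPe:
    baseline_F: 1.0
    noise_sd: 0.02
    kernels:
      go_cue:
        amplitude: 0.25
        rise_tau: 0.05
        decay_tau: 0.4
      stop_cue:
        amplitude: 0.3
        rise_tau: 0.05
        decay_tau: 0.4
      feedback:
        amplitude: 0.6
        rise_tau: 0.05
        decay_tau: 0.4
      reward:
        amplitude: 0.7
        rise_tau: 0.1
        decay_tau: 1.0
      volitional_ramp:
        amplitude: 0.6
        rise_tau: 0.3
        decay_tau: 1.0
  STN:
    baseline_F: 1.0
    noise_sd: 0.02
    kernels:
      go_cue:
        amplitude: 0.25
        rise_tau: 0.05
        decay_tau: 0.4
      stop_cue:
        amplitude: 0.3
        rise_tau: 0.05
        decay_tau: 0.4
      feedback:
        amplitude: 0.55
        rise_tau: 0.05
        decay_tau: 0.4
      reward:
        amplitude: 0.65
        rise_tau: 0.1
        decay_tau: 1.0
      volitional_ramp:
        amplitude: 0.55
        rise_tau: 0.3
        decay_tau: 1.0
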
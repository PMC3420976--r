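# Simulate the before/after ttc discrimination experiment for the default
# seven-ttc / five-presentation-time / two-size design.
pipeline: simulate
design:
  ttc_levels: [2.0, 2.25, 2.5, 2.75, 3.0, 3.25, 3.5]  # package default, overridable
  presentation_levels: [0.5, 0.85, 1.2, 1.55, 1.9]    # package default, overridable
  t_ref: 2.75                                          # package default, overridable
  d0_range: [4.0, 8.0]                                 # package default, overridable
  dt: 0.001
xi:
  mu: 1.0
  w: 1.0
  xi_theta: 0.75
  xi_theta_dot: 0.75
noise:
  p_theta: 0.3
  p_theta_dot: 0.3
  noise_mode: relative
n_avg: 50            # package default, overridable
n_trials: 200
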
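# Sample a clean approach trace and evaluate tau / m-Tau / Xi on it.
pipeline: kinematics
stimulus:
  half_size_m: 0.05     # sphere radius (m); or give diameter_m
  speed_m_s: 2.0
  ttc_s: 3.0
  dt_s: 0.001
xi:
  mu: 1.0               # package default, overridable
  w: 1.0
  xi_theta: 0.75        # package default, overridable
  xi_theta_dot: 0.75    # package default, overridable
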
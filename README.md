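# loomtau

Models of visual looming for time-to-contact (ttc) estimation and collision
detection, built around the *corrected modified tau* framework.

## The problem

An object on a direct collision course projects a symmetrically expanding
image on the retina. Two phenomenological models dominate the literature on
how nervous systems use that expansion:

- the **tau function**, `tau = theta / theta_dot` (angular size over
  expansion rate), which approximates the remaining time to contact
  `tc - t` for small angles and underlies interceptive timing;
- the **eta function**, `eta = C * theta_dot * exp(-alpha * theta)`, which
  describes collision-sensitive neurons (locust LGMD/DCMD and relatives):
  it peaks *before* contact, at the fixed angular size
  `2 * atan(1 / alpha)`, so the peak delay is linear in the half-size-to-
  speed ratio `x = l / |v|`.

The **modified tau** (m-Tau) bridges the two: `m_tau = theta / (mu +
theta_dot)`, with a leakage constant `mu` (rad/s) that creates an eta-like
pre-contact maximum at distance `d = sqrt(R^2 + 2 R v / mu)`. Adding back a
low-pass-filtered correction term gives the **corrected m-Tau (Xi)**:

    Xi = theta / (mu + theta_dot)
       + w * mu * lp(theta) / (lp(theta_dot) * (mu + lp(theta_dot)) + eps)
       + kappa

which restores the ttc-estimation property of tau while suppressing noise.
Its behaviour is bounded by two limit functions: ordinary tau (small `mu`)
and tau computed from low-pass-filtered angular variables (large `mu`).

The package implements, with seeded synthetic-data generators throughout:

- closed-form optics of rigid-sphere constant-velocity approaches and trace
  generation (`approach_stimulus`, `generate_trace`);
- the function family and its closed-form / numeric peak analysis
  (`tau_fun`, `eta_fun`, `m_tau_fun`, `corrected_m_tau`, `lp_tau`,
  `m_tau_peak_closed_form`, `eta_peak_closed_form`, `numeric_peak`);
- noisification of the optical variables (`noise_spec`, `noisify_trace`);
- the noise-masked linearity analysis of peak times versus `l/|v|`
  (`masking_experiment`, `weighted_line_fit`, `intercept_slope_ellipse`);
- a simulator of before/after ttc discrimination experiments with
  Gaussian-CDF psychometric fits (`proportion_later`, `fit_gcdf`);
- exhaustive grid-search parameter optimization with rmse and a robust
  error score (`grid_search`, `combine_rank`, `median_noise_by_rank`);
- nonlinear fits of looming functions to firing-rate curves
  (`fit_model_to_trace`, `peak_linearity_report`).

## Worked example

```r
library(loomtau)

# a 10 cm sphere approaching at 2 m/s, contact after 3 s
stim <- approach_stimulus(half_size_R = 0.05, speed_v = 2,
                          collision_time_tc = 3)

# closed-form m-Tau peak for mu = 1 rad/s
pk <- m_tau_peak_closed_form(stim, mu = 1)
pk$d_hat                     # 0.45  (peak distance, m)
stim$collision_time_tc - pk$t_peak   # 0.225 (peak delay before contact, s)

# eta peaks at a fixed angular size, independent of speed
eta_peak_closed_form(stim, eta_params(alpha = 1))$theta_at_peak  # 1.5708 = pi/2

# a noisy ttc estimate from the Xi observer
tr  <- noisify_trace(generate_trace(stim, 0, 1), noise_spec(0.2, 0.2, seed = 1))
est <- ttc_estimate(corrected_m_tau(tr, xi_params(mu = 1, w = 1)),
                    tr$times, trial_config(1, 2.75, n_avg = 50))
est$predicted_contact        # 2.952 s, close to the true contact at 3 s
```

The peak distance `0.45 m` is `sqrt(R^2 + 2 R v / mu)`; the peak delay
`0.225 s` is that distance divided by the speed. The eta peak angle `pi/2`
follows from `2 * atan(1/alpha)` with `alpha = 1`.

A shell entry point for the main pipelines is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/loomtau", package = "loomtau"))')" \
  simulate --config inst/extdata/example_simulate.yaml --out out/ --seed 1
```

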
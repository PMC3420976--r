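---
title: "Methods: the corrected modified tau framework in loomtau"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the corrected modified tau framework in loomtau}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomtau)
```

## The model family

A rigid sphere of half-size (radius) $R$ approaching head-on at constant
speed $v$ reaches the observer at time $t_c$; its distance is
$d(t) = v\,(t_c - t)$. The optical variables are the full subtended angle
$\theta = 2\arctan(R/d)$, its rate $\dot\theta = 2Rv/(d^2+R^2)$, and the
angular acceleration $\ddot\theta = 4Rv^2 d/(d^2+R^2)^2$. All internal
angles are radians; degree conversion happens only at I/O boundaries.
Traces never include $t \ge t_c$, where the optical variables lose meaning.

From these, the package evaluates:

* $\tau = \theta/\dot\theta$ — approximately the remaining time
  $t_c - t$ for small angles; it is not monotone all the way to contact but
  attains a minimum at $d = kR$ with $k$ the root of $2k\arctan(1/k) = 1$
  ($k \approx 0.42898$, computed by `tau_min_ratio()`).
* $\eta = C\,\dot\theta\,e^{-\alpha\theta}$ — the standard model of
  collision-sensitive neurons; it peaks exactly where $d = \alpha R$, i.e.
  at the fixed angular size $2\arctan(1/\alpha)$ and with peak delay
  $\alpha R/v + \delta$ before contact ($\delta$ a temporal delay).
* m-Tau $= \theta/(\mu + \dot\theta)$ — $\tau$ damped by a leakage
  constant $\mu$ (rad/s). Under the small-angle approximation
  $\tau \approx t_c - t$, its maximum lies at distance
  $\hat d = \sqrt{R^2 + 2Rv/\mu}$; the closed-form peak is exposed through
  `m_tau_peak_closed_form()` under exactly this approximation, while the
  exact-trace peak is only available numerically (`numeric_peak()`).
* the corrected m-Tau (Xi):
  $\Xi = \dfrac{\theta}{\mu+\dot\theta} +
  w\,\dfrac{\mu\,\hat\theta}{\hat{\dot\theta}\,(\mu+\hat{\dot\theta})+\varepsilon} + \kappa$,
  where $\hat\theta,\hat{\dot\theta}$ are first-order low-pass filtered
  versions of the angular variables.

Algebraically, $\mu\theta/(\dot\theta(\mu+\dot\theta))$ equals
$\tau - \text{m-Tau}$, so with $w = 1$, no filtering and
$\varepsilon = \kappa = 0$, $\Xi \equiv \tau$; with $w = 0$ it is m-Tau.
These identities anchor the test suite. The correction term applies the
filters to the two angular variables separately before recombination — the
reading under which "low-pass filtering of $\theta$ and $\dot\theta$"
turns the correction into a slowly varying signal — rather than filtering
the assembled term. The weight $w$ multiplies the filtered correction so
that a single parameter switches between eta-like ($w=0$) and tau-like
($w=1$) behaviour, and a single $\mu$ then sweeps $\Xi$ between its two
limit functions: ordinary $\tau$ for $\mu \to 0$ and
$\hat\theta/\hat{\dot\theta}$ (`lp_tau()`) for large $\mu$.

## Filters and numerical choices

The discrete low-pass filter is
$\hat x_k = \xi\,\hat x_{k-1} + (1-\xi)\,x_k$ with memory coefficient
$\xi \in [0,1)$; $\xi = 0$ reproduces the input. The update uses the
*current* input sample, avoiding a one-sample dead time in Xi. Filters are
initialised with the first trace samples, so there are no start-up
transients. Both filter states feed the correction term only; the m-Tau
head term keeps the raw variables.

* $\varepsilon$ defaults to $10^{-12}$ and guards the product
  $\hat{\dot\theta}(\mu + \hat{\dot\theta})$; its exact placement is a
  package choice. Samples of a noisy trace where $\mu + \dot\theta \le 0$
  are evaluated with the guarded denominator and flagged.
* $\kappa$ defaults to 0 (it is negligible in practice) and is retained
  only as a searchable offset for the optimization module.
* The default sampling step is 1 ms, fine enough to resolve every filter
  time constant used here.
* `numeric_peak()` refines the grid argmax with a three-point parabolic
  interpolation; ties between equal interior maxima break to the earliest
  sample, and boundary maxima are flagged rather than refined.

## Noise model

`noisify_trace()` perturbs each channel independently with centred normal
deviates: multiplicatively ($x(1 + pN)$, default) or additively
($x + pN$). The relative form is the default because it keeps the blur of
a small object proportionally the same along the whole approach, which is
the reading most consistent with noise levels described as per-variable
probabilities in $[0,1]$; the additive form is retained as an explicit
mode because noise can equally be described as being added to the angular
variables. The choice is always recorded in the `noise_spec`. Each trial
draws from a deterministically derived sub-stream (a SplitMix-style
integer hash of seed, trial and channel), so trial $i$ is reproducible
regardless of how many trials run before it.

## Psychophysics simulator

The simulated observer sees an approach for a presentation time $t_p$,
evaluates Xi on the noisified optical variables, averages the last
$n$ samples up to and including $t_p$ (inclusive window; robust windowed
estimate), and judges "later" when $t_p$ plus that estimate exceeds the
reference time — exact ties count as "before". Proportions of later
responses per (ttc, size, presentation-time) condition are summarised by
least-squares Gaussian-CDF fits (`fit_gcdf()`), whose mean is the point of
subjective simultaneity (PSE) and whose spread is bounded below by the
sampling step; a binomial-likelihood fit is deliberately not the default
because the observations enter the optimization unweighted. No lapse or
guess rates are added: the simulated observer has none.

Default design (magnitudes are package choices, all overridable): seven
ttc levels 2.00–3.50 s in 0.25 s steps, reference 2.75 s, five
presentation times 0.5–1.9 s, object diameters 0.04 and 0.08 m, starting
distances drawn once per condition uniformly from 4–8 m (speeds then
follow as $d_0/t_c$, about 1.1–4 m/s — a realistic indoor interception
range), $n = 50$ window samples at 1 ms, 200 trials per condition. The
presentation times stop just below the shortest ttc because a stimulus
cannot remain visible past its own contact time.

The default observer uses $\mu = 1$, $w = 1$ and moderate filtering
$\xi_\theta = \xi_{\dot\theta} = 0.75$. Moderate (rather than near-total)
filtering matters: with very strong filtering the windowed estimate
becomes essentially unbiased at every presentation time, whereas the
ratio $\hat\theta/\hat{\dot\theta}$ of partially filtered noisy variables
carries a small positive (Jensen) bias proportional to the remaining
time. That bias is what makes the simulated PSE drift toward the
reference as the presentation time grows — the qualitative signature the
simulator is meant to emulate. Study noise levels for the synthetic
observer are 0.4 (small object) and 0.2 (big), in relative mode.

What the generator does *not* emulate: lapses, response-time dynamics,
learning between sessions, or binocular cues. Passing tests therefore
show that the estimator and simulator behave as derived — not that human
observers lack those extra processes.

## Grid-search optimization

The observer has eight free parameters
($\mu, w, \xi_\theta, \xi_{\dot\theta}, \kappa, p_\theta, p_{\dot\theta}, n$;
$\varepsilon$ is fixed). `grid_search()` enumerates a constant-step grid
in deterministic lexicographic order, simulates each cell's psychometric
curves with common random numbers (one shared simulation seed across
cells, which removes simulation noise from the ranking), and scores each
cell against the small- and big-object observations with two measures:
the unweighted root mean square error and a robust error whose default
aggregate is the median absolute residual (mean absolute deviation and a
20%-trimmed mean are selectable; the choice is recorded in the outputs).
Scores are ranked ascending, ties keeping enumeration order; per-size
tables are combined by averaging the two scores per cell and re-ranking,
which necessarily trades off against either size's individual best.
`median_noise_by_rank()` summarises the noise levels of the top-$k$ cells
by the median with a normal-consistent MAD spread. Reduced models are
expressed as grid restrictions ($w = 0$; or both filter memories 0), so
model comparison is a grid operation, not special-cased code.

## Noise-masked linearity analysis

The closed-form m-Tau peak delay over the stimulus ratio $x = R/v$ is
$\sqrt{x^2 + 2x/\mu}$ — intrinsically nonlinear, with local slope
$(x + 1/\mu)/\sqrt{x^2+2x/\mu}$ falling toward 1 as $\mu$ or $x$ grows.
`masking_experiment()` adds ratio-proportional Gaussian noise
($\sigma(x) = c\,x$, default $c = 0.15$; the proportionality mirrors how
measurement spread grows with the stimulus ratio), averages 25 trials per
ratio, fits a weighted least-squares line (weights = inverse variance of
the trial means), and repeats. A repeat counts as "masked" when residual
normality is not rejected (Lilliefors $p > 0.05$ — the strictest single
gate among the diagnostics, which all get reported: $r^2$, the
KS-type test and the regression F test) while the slope is significant.
The default ratio grid is 10 log-spaced points over one decade. The
covariance ellipse of intercept–slope pairs uses the eigenvectors of the
2×2 sample covariance with axes scaled by the square roots of the
eigenvalues (a one-standard-deviation ellipse).

## Response fitting

`fit_model_to_trace()` fits $A\,f(t;\text{shape}, \delta) + b$ to a
firing-rate trace indexed by time relative to collision, where $f$ is the
stimulus function of eta, m-Tau, inverse tau or angular acceleration. A
positive delay $\delta$ advances the response peak, so the peak-delay
regression of $t_c - t_\text{peak}$ on $x$ has intercept $+\delta$ —
matching the identification of the line-fit intercept with a temporal
delay. For inverse tau and angular acceleration no shape parameter can
shift the peak; only amplitude, delay and baseline are free, which is why
their fixed slopes ($\approx 0.42898$ and $1/\sqrt{3} \approx 0.57735$)
underestimate eta-like data with larger $\alpha$. Initialisation is
multi-start: shape log-spaced over four decades, amplitude and baseline
solved linearly per start, delay and shape polished by Nelder–Mead, ties
in SSE resolved toward the smaller shape. A baseline is always allowed
because recordings typically decay to a nonzero resting rate. Goodness of
fit reports rmse, $r^2$ and the F statistic against the constant-mean
model with conventional degrees of freedom.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the identity suite on 100
random stimuli (300-sample traces), the peak oracle on 50 random
small-angle stimuli (2000-sample traces), the masking experiment with 25
trials × 100 repeats, the variance comparison on 100 noisy traces, the
psychometric surface at the full default design with 200 trials per
condition, grid recovery on an 81-cell grid × 20 seeded repeats with
40 trials per condition at 10 ms sampling, and 50 noisy response fits.
These sizes were chosen as the smallest at which the Monte-Carlo
properties are stable across seeds.

## Known limitations

* Closed-form peak formulas assume the small-angle approximation; for
  stimuli with $R/d_0 > 0.01$ use the numeric peak of the exact series.
* The biophysical firing-rate equation from which m-Tau derives (and its
  inhibitory extension) is out of scope; only the equilibrium function
  family is implemented.
* The grid search is exhaustive by design — the cost grows as the product
  of the per-parameter level counts; restrict parameters via single-value
  grid entries rather than shrinking steps.
* Temporally correlated noise and spiking (Poisson) noise are not
  modelled.
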
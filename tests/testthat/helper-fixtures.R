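# Shared fixtures: small, fast stimuli and an independent brute-force peak
# oracle used to freeze expected values.

std_stim <- function(R = 0.05, v = 2, tc = 3, dt = 1e-3)
  approach_stimulus(half_size_R = R, speed_v = v, collision_time_tc = tc, dt = dt)

# Independent grid-argmax oracle: evaluates fn(d) on a dense distance grid
# and returns the distance of the maximum (no parabolic refinement, no
# package peak code).
brute_force_argmax_d <- function(fn, d_max, n = 1e4) {
  d <- seq(d_max / n, d_max, length.out = n)
  d[which.max(fn(d))]
}

# Small design for fast psychophysics tests (coarser dt, fewer levels).
tiny_design <- function(dt = 0.01)
  experiment_design(ttc_levels = seq(2.0, 3.5, by = 0.25),
                    presentation_levels = c(0.5, 1.0, 1.5),
                    dt = dt, design_seed = 11L)
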
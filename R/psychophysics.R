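#' Trial configuration for the discrimination simulator
#'
#' @param presentation_time_tp Stimulus presentation time (s); the approach
#'   is shown on [0, t_p] and then blanked.
#' @param reference_time_tref Reference contact time (s) against which the
#'   simulated observer judges "ball hit me after / before".
#' @param n_avg Number of samples in the averaging window ending at t_p; the
#'   windowed mean makes the ttc estimate robust.
#' @param n_trials Trials per condition.
#' @param dt Sampling step (s).
#' @return An object of class \code{"trial_config"}.
#' @export
trial_config <- function(presentation_time_tp, reference_time_tref,
                         n_avg = 50L, n_trials = 200L, dt = 0.001) {
  if (presentation_time_tp <= 0) stop("presentation_time_tp must be positive")
  if (n_avg < 1L) stop("n_avg must be a positive integer")
  if (n_trials < 1L) stop("n_trials must be a positive integer")
  if (n_avg * dt > presentation_time_tp)
    stop("averaging window (n_avg * dt) exceeds the presentation time")
  structure(list(presentation_time_tp = presentation_time_tp,
                 reference_time_tref = reference_time_tref,
                 n_avg = as.integer(n_avg), n_trials = as.integer(n_trials),
                 dt = dt),
            class = "trial_config")
}

#' Windowed time-to-contact estimate from a Xi series
#'
#' Averages the last \code{n_avg} samples of the series up to and including
#' the presentation time to obtain a robust remaining-time estimate; the
#' predicted contact time is \code{t_p + mean}.  The within-window standard
#' deviation is reported alongside.
#'
#' @param xi_series Sampled Xi (or any ttc-estimating) signal, seconds.
#' @param times Sample times matching \code{xi_series}.
#' @param cfg A \code{\link{trial_config}}.
#' @return List with \code{mean_estimate}, \code{sd_estimate} (both s) and
#'   \code{predicted_contact = t_p + mean_estimate}.
#' @export
ttc_estimate <- function(xi_series, times, cfg) {
  tp <- cfg$presentation_time_tp
  i_end <- max(which(times <= tp + 1e-12))
  i_start <- i_end - cfg$n_avg + 1L
  if (i_start < 1L) stop("series does not cover the averaging window")
  win <- xi_series[i_start:i_end]
  m <- mean(win)
  list(mean_estimate = m,
       sd_estimate = if (cfg$n_avg > 1L) stats::sd(win) else 0,
       predicted_contact = tp + m)
}

#' Simulate one before/after ttc discrimination trial
#'
#' Generates a clean optical trace on [0, t_p], noisifies it with a sub-seed
#' derived from the noise spec's seed and the trial index, evaluates the
#' corrected m-Tau observer, forms the windowed ttc estimate and compares the
#' predicted contact time against the reference time.  An exact tie counts
#' as "before".
#'
#' @param stim An \code{\link{approach_stimulus}}.
#' @param xi An \code{\link{xi_params}}.
#' @param noise A \code{\link{noise_spec}}.
#' @param cfg A \code{\link{trial_config}}.
#' @param trial_index Trial number (reproducible sub-stream).
#' @return Logical: did the simulated observer answer "later"?
#' @export
simulate_trial <- function(stim, xi, noise, cfg, trial_index = 1L) {
  tr <- generate_trace(stim, 0, cfg$presentation_time_tp)
  tr <- noisify_trace(tr, noise, trial_index = trial_index)
  xi_series <- corrected_m_tau(tr, xi)
  est <- ttc_estimate(xi_series, tr$times, cfg)
  est$predicted_contact > cfg$reference_time_tref
}

# All trials of one condition at once: clean trace shared, noise per trial.
# Returns list(prop_later, mean_sd).
simulate_condition <- function(stim, xi, noise, cfg) {
  tr <- generate_trace(stim, 0, cfg$presentation_time_tp)
  trials <- seq_len(cfg$n_trials)
  th <- noisify_channel_trials(tr$theta, noise$p_theta, noise$mode,
                               noise$seed, 1L, trials)
  thd <- noisify_channel_trials(tr$theta_dot, noise$p_theta_dot, noise$mode,
                                noise$seed, 2L, trials)
  if (noise$floor_at_zero) {
    th[th < 0] <- 0
    thd[thd < 0] <- 0
  }
  xi_m <- corrected_m_tau_mat(th, thd, xi)
  n <- nrow(xi_m)
  i_end <- max(which(tr$times <= cfg$presentation_time_tp + 1e-12))
  win <- xi_m[(i_end - cfg$n_avg + 1L):i_end, , drop = FALSE]
  est <- colMeans(win)
  pred <- cfg$presentation_time_tp + est
  sds <- if (cfg$n_avg > 1L) apply(win, 2, stats::sd) else rep(0, ncol(win))
  list(prop_later = mean(pred > cfg$reference_time_tref),
       mean_sd = mean(sds))
}

#' Experimental design of the ttc discrimination experiment
#'
#' Default magnitudes mirror the shape of the original design (seven ttc
#' levels, five presentation times, two object sizes, varied starting
#' distances) with configurable values.
#'
#' @param ttc_levels Contact times (s) presented, default seven levels
#'   2.00-3.50 s.
#' @param size_levels Named half-sizes (m) for the \code{small} and
#'   \code{big} objects (defaults: diameters 0.04 and 0.08 m).
#' @param presentation_levels Presentation times (s), default five levels
#'   0.5-1.9 s; every presentation time must end before the shortest ttc,
#'   otherwise the earliest approaches would reach contact while still
#'   visible.
#' @param t_ref Reference contact time (s), default 2.75 s.
#' @param d0_range Interval (m) from which the initial starting distance of
#'   each condition is drawn uniformly; the speed follows as
#'   \code{v = d0 / ttc}.
#' @param dt Sampling step (s).
#' @param design_seed Seed for the per-condition distance draws.
#' @return An object of class \code{"experiment_design"}.
#' @export
experiment_design <- function(ttc_levels = seq(2.0, 3.5, by = 0.25),
                              size_levels = c(small = 0.02, big = 0.04),
                              presentation_levels = seq(0.5, 1.9, by = 0.35),
                              t_ref = 2.75,
                              d0_range = c(4, 8),
                              dt = 0.001,
                              design_seed = 1L) {
  if (any(presentation_levels >= min(ttc_levels)))
    stop("every presentation time must be shorter than the shortest ttc")
  if (length(size_levels) != 2L || is.null(names(size_levels)))
    stop("size_levels must be a named pair (small, big)")
  if (any(size_levels <= 0) || any(d0_range <= 0))
    stop("sizes and distances must be positive")
  structure(list(ttc_levels = ttc_levels, size_levels = size_levels,
                 presentation_levels = presentation_levels, t_ref = t_ref,
                 d0_range = d0_range, dt = dt,
                 design_seed = as.integer(design_seed)),
            class = "experiment_design")
}

# Deterministic per-condition starting distance in d0_range.
condition_d0 <- function(design, i_ttc, i_size, i_tp) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(design$design_seed, i_ttc, i_size, i_tp))
  stats::runif(1, design$d0_range[1], design$d0_range[2])
}

#' Proportion-of-later curves for a full design
#'
#' Runs \code{n_trials} independent simulated trials for every
#' (ttc, size, presentation time) condition of the design and returns the
#' fraction of "later" responses per condition, plus the mean within-window
#' estimate spread for display bands.
#'
#' @param design An \code{\link{experiment_design}}.
#' @param xi An \code{\link{xi_params}} describing the observer.
#' @param noise A \code{\link{noise_spec}}.
#' @param n_avg Averaging-window length in samples.
#' @param n_trials Trials per condition.
#' @return Data frame of psychometric points: \code{ttc_s, tp_s, size_label,
#'   prop_later, n_trials, est_sd_s}.
#' @export
proportion_later <- function(design, xi, noise, n_avg = 50L, n_trials = 200L) {
  rows <- list()
  r <- 0L
  for (i_tp in seq_along(design$presentation_levels)) {
    tp <- design$presentation_levels[i_tp]
    cfg <- trial_config(tp, design$t_ref, n_avg = n_avg,
                        n_trials = n_trials, dt = design$dt)
    for (i_size in seq_along(design$size_levels)) {
      for (i_ttc in seq_along(design$ttc_levels)) {
        tc <- design$ttc_levels[i_ttc]
        d0 <- condition_d0(design, i_ttc, i_size, i_tp)
        stim <- approach_stimulus(half_size_R = design$size_levels[i_size],
                                  speed_v = d0 / tc, collision_time_tc = tc,
                                  dt = design$dt)
        # condition-specific noise sub-stream so trials never repeat across
        # conditions but remain reproducible
        nz <- noise
        nz$seed <- derive_seed(noise$seed, i_ttc, i_size, i_tp)
        sim <- simulate_condition(stim, xi, nz, cfg)
        r <- r + 1L
        rows[[r]] <- data.frame(
          ttc_s = tc, tp_s = tp,
          size_label = names(design$size_levels)[i_size],
          prop_later = sim$prop_later, n_trials = n_trials,
          est_sd_s = sim$mean_sd)
      }
    }
  }
  do.call(rbind, rows)
}

#' Fit a Gaussian cumulative density function to psychometric points
#'
#' Least-squares fit of \code{pnorm((ttc - m) / s)} to the proportion-of-later
#' responses of one size and presentation time.  \code{m} is the point of
#' subjective simultaneity (PSE); \code{s} is the spread of the underlying
#' psychometric curve.  Initialisation uses the 50% crossing of the linear
#' interpolation; \code{s} is bounded below by the sampling step.
#'
#' @param points Data frame with columns \code{ttc_s} and \code{prop_later}
#'   (one size and presentation time, >= 3 distinct ttc levels).
#' @param dt Lower bound for the fitted spread (s); default 1 ms.
#' @return List of class \code{"gcdf_fit"}: \code{pse_mean}, \code{sd},
#'   \code{sse}, \code{degenerate} flag.
#' @export
fit_gcdf <- function(points, dt = 0.001) {
  x <- points$ttc_s
  y <- points$prop_later
  if (length(unique(x)) < 3L) stop("need >= 3 distinct ttc levels")
  if (any(y < 0 | y > 1)) stop("proportions must lie in [0, 1]")
  degenerate <- diff(range(y)) < .Machine$double.eps^0.5
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  # init: 50% crossing of the linear interpolation, spread from the 25-75% span
  m0 <- if (!degenerate && any(yo <= 0.5) && any(yo >= 0.5)) {
    tryCatch(stats::approx(yo, xo, xout = 0.5, ties = mean)$y,
             error = function(e) mean(xo))
  } else mean(xo)
  if (!is.finite(m0)) m0 <- mean(xo)
  s0 <- max(diff(range(xo)) / 4, dt)
  obj <- function(par) {
    s <- dt + exp(par[2])
    sum((stats::pnorm((x - par[1]) / s) - y)^2)
  }
  fit <- stats::optim(c(m0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(pse_mean = fit$par[1], sd = dt + exp(fit$par[2]),
                 sse = fit$value, degenerate = degenerate,
                 converged = fit$convergence == 0),
            class = "gcdf_fit")
}

#' @export
print.gcdf_fit <- function(x, ...) {
  cat(sprintf("GCDF fit: PSE = %.4f s, spread = %.4f s, SSE = %.3g%s\n",
              x$pse_mean, x$sd, x$sse,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Synthetic observer dataset
#'
#' Ground-truth fixture generator: runs \code{\link{proportion_later}} under a
#' stated true observer parameterization and returns the psychometric table.
#' Used as the recovery target for the optimization module.  Optionally takes
#' size-specific noise levels (the smaller object may be noisier).
#'
#' @param xi True \code{\link{xi_params}}.
#' @param noise True \code{\link{noise_spec}}; for size-specific noise give a
#'   named list \code{list(small = spec, big = spec)}.
#' @param design An \code{\link{experiment_design}}.
#' @param n_avg,n_trials Window length and trials per condition.
#' @return Psychometric data frame as from \code{\link{proportion_later}}.
#' @export
synth_observer_dataset <- function(xi, noise, design, n_avg = 50L,
                                   n_trials = 200L) {
  if (inherits(noise, "noise_spec")) {
    return(proportion_later(design, xi, noise, n_avg, n_trials))
  }
  stopifnot(all(c("small", "big") %in% names(noise)))
  out <- lapply(c("small", "big"), function(lab)
    proportion_later_single_size(design, lab, xi, noise[[lab]],
                                 n_avg, n_trials))
  do.call(rbind, out)
}

# proportion_later restricted to one size label, preserving the condition
# sub-stream indexing of the full design.
proportion_later_single_size <- function(design, size_label, xi, noise,
                                         n_avg = 50L, n_trials = 200L) {
  i_size <- match(size_label, names(design$size_levels))
  if (is.na(i_size)) stop("unknown size label: ", size_label)
  rows <- list(); r <- 0L
  for (i_tp in seq_along(design$presentation_levels)) {
    tp <- design$presentation_levels[i_tp]
    cfg <- trial_config(tp, design$t_ref, n_avg = n_avg,
                        n_trials = n_trials, dt = design$dt)
    for (i_ttc in seq_along(design$ttc_levels)) {
      tc <- design$ttc_levels[i_ttc]
      d0 <- condition_d0(design, i_ttc, i_size, i_tp)
      stim <- approach_stimulus(half_size_R = design$size_levels[[i_size]],
                                speed_v = d0 / tc, collision_time_tc = tc,
                                dt = design$dt)
      nz <- noise
      nz$seed <- derive_seed(noise$seed, i_ttc, i_size, i_tp)
      sim <- simulate_condition(stim, xi, nz, cfg)
      r <- r + 1L
      rows[[r]] <- data.frame(ttc_s = tc, tp_s = tp, size_label = size_label,
                              prop_later = sim$prop_later,
                              n_trials = n_trials, est_sd_s = sim$mean_sd)
    }
  }
  do.call(rbind, rows)
}
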
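#' Firing-rate trace of a collision-sensitive neuron
#'
#' Time series of the response of an LGMD/DCMD-like looming detector to a
#' constant-velocity approach, indexed by time relative to collision
#' (negative before contact).
#'
#' @param times Times relative to collision (s), strictly increasing and
#'   negative before contact.
#' @param rate Response per sample (spikes/s or arbitrary units).
#' @param stim_half_size Object half-size (m).
#' @param stim_speed Approach speed (m/s).
#' @return An object of class \code{"firing_rate_trace"}; the derived
#'   \code{x_ratio = stim_half_size / stim_speed} (s) is attached.
#' @export
firing_rate_trace <- function(times, rate, stim_half_size, stim_speed) {
  if (length(times) != length(rate))
    stop("times and rate must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (stim_half_size <= 0 || stim_speed <= 0)
    stop("stimulus half-size and speed must be positive")
  structure(list(times = times, rate = rate,
                 stim_half_size = stim_half_size, stim_speed = stim_speed,
                 x_ratio = stim_half_size / stim_speed),
            class = "firing_rate_trace")
}

#' @export
print.firing_rate_trace <- function(x, ...) {
  cat(sprintf(
    "Firing-rate trace: %d samples, t in [%g, %g] s rel. collision, l/|v| = %g s\n",
    length(x$times), x$times[1], x$times[length(x$times)], x$x_ratio))
  invisible(x)
}

# Stimulus functions of the registered models, evaluated at times relative
# to collision.  A positive delay delta advances the response peak (further
# before contact), so that tc - t_peak = shape * R/v + delta; remaining is
# the stimulus' remaining time to contact at the shifted instant.
model_shape <- function(model_name, t_rel, R, v, shape, delta) {
  remaining <- -(t_rel + delta)
  remaining <- pmax(remaining, 1e-9)  # guard at/after shifted contact
  d <- v * remaining
  th <- 2 * atan(R / d)
  thd <- 2 * R * v / (d^2 + R^2)
  switch(model_name,
         eta = thd * exp(-shape * th),
         m_tau = th / (shape + thd),
         inverse_tau = thd / th,
         theta_ddot = 4 * R * v^2 * d / (d^2 + R^2)^2,
         stop("unknown model: ", model_name))
}

model_has_shape <- function(model_name)
  model_name %in% c("eta", "m_tau")

#' Fit a looming-function model to a firing-rate trace
#'
#' Nonlinear least squares of \code{A * f(t - delta; shape) + baseline} to
#' the rate, where \code{f} is the stimulus function of the chosen model
#' (\code{eta}, \code{m_tau}, \code{inverse_tau} or \code{theta_ddot}).  For
#' \code{inverse_tau} and \code{theta_ddot} there is no shape parameter that
#' could shift the peak; only amplitude, delay and baseline are free.
#'
#' Fitting uses multi-start initialisation: the shape parameter is seeded
#' log-spaced over four decades, amplitude and baseline are solved linearly
#' for each (shape, delay) by least squares, and the delay/shape pair is
#' polished by Nelder-Mead.  Ties in SSE break to the smaller shape value.
#'
#' @param trace A \code{\link{firing_rate_trace}}.
#' @param model_name One of \code{"eta"}, \code{"m_tau"},
#'   \code{"inverse_tau"}, \code{"theta_ddot"}.
#' @param shape_bounds Search range for the shape parameter (alpha or mu).
#' @param delta_bounds Search range for the delay (s).
#' @param n_starts Number of log-spaced shape starts.
#' @return A list of class \code{"fit_result"}: \code{model_name},
#'   \code{fitted_params} (amplitude, delay, baseline and \code{alpha} or
#'   \code{mu} where applicable), goodness of fit (\code{rmse}, \code{r2},
#'   \code{f_stat}, \code{f_p}), predicted and observed peak times
#'   (\code{t_peak_pred}, \code{t_peak_obs}, relative to collision) and a
#'   \code{converged} flag.
#' @export
fit_model_to_trace <- function(trace, model_name = c("eta", "m_tau",
                                                     "inverse_tau", "theta_ddot"),
                               shape_bounds = c(1e-2, 1e2),
                               delta_bounds = c(-0.5, 0.5),
                               n_starts = 9L) {
  model_name <- match.arg(model_name)
  stopifnot(inherits(trace, "firing_rate_trace"))
  t_rel <- trace$times; y <- trace$rate
  R <- trace$stim_half_size; v <- trace$stim_speed
  n <- length(y)
  if (n < 5L) stop("trace too short to fit")
  if (stats::sd(y) == 0) stop("rank-deficient data: constant rate trace")

  # linear amplitude/baseline solve for fixed (shape, delta)
  sse_of <- function(shape, delta) {
    f <- model_shape(model_name, t_rel, R, v, shape, delta)
    X <- cbind(f, 1)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(list(sse = Inf))
    resid <- y - X %*% cf
    list(sse = sum(resid^2), A = cf[1], baseline = cf[2])
  }

  has_shape <- model_has_shape(model_name)
  shape_starts <- if (has_shape) {
    exp(seq(log(shape_bounds[1]), log(shape_bounds[2]), length.out = n_starts))
  } else NA_real_

  best <- NULL
  for (s0 in shape_starts) {
    if (has_shape) {
      obj <- function(par) sse_of(exp(par[1]), par[2])$sse
      op <- stats::optim(c(log(s0), 0), obj, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-14))
      cand <- list(shape = exp(op$par[1]), delta = op$par[2],
                   sse = op$value, converged = op$convergence == 0)
    } else {
      obj <- function(par) sse_of(NA, par[1])$sse
      op <- stats::optim(0, obj, method = "Brent",
                         lower = delta_bounds[1], upper = delta_bounds[2])
      cand <- list(shape = NA_real_, delta = op$par[1], sse = op$value,
                   converged = op$convergence == 0)
    }
    if (is.null(best) || cand$sse < best$sse - 1e-15 ||
        (abs(cand$sse - best$sse) <= 1e-15 && has_shape &&
         !is.na(best$shape) && cand$shape < best$shape)) {
      best <- cand
    }
    if (!has_shape) break  # no shape starts needed
  }

  lin <- sse_of(best$shape, best$delta)
  pars <- list(amplitude = unname(lin$A), delay = best$delta,
               baseline = unname(lin$baseline))
  if (model_name == "eta") pars$alpha <- best$shape
  if (model_name == "m_tau") pars$mu <- best$shape

  f <- model_shape(model_name, t_rel, R, v, best$shape, best$delta)
  pred <- pars$amplitude * f + pars$baseline
  n_params <- 3L + has_shape
  gof <- goodness_of_fit(y, pred, n_params)

  pk_obs <- numeric_peak(y, t_rel)
  pk_pred <- numeric_peak(pred, t_rel)

  structure(c(list(model_name = model_name, fitted_params = pars,
                   t_peak_pred = pk_pred$t_peak, t_peak_obs = pk_obs$t_peak,
                   x_ratio = trace$x_ratio,
                   converged = isTRUE(best$converged)),
              gof),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit: %s\n", x$model_name))
  p <- x$fitted_params
  cat("  params:", paste(sprintf("%s = %.5g", names(p), unlist(p)),
                         collapse = ", "), "\n")
  cat(sprintf("  rmse = %.4g, r2 = %.4f, F = %.4g (p = %.3g)\n",
              x$rmse, x$r2, x$f_stat, x$f_p))
  cat(sprintf("  peak (rel. collision): predicted %.4f s, observed %.4f s\n",
              x$t_peak_pred, x$t_peak_obs))
  invisible(x)
}

#' Goodness-of-fit statistics
#'
#' Root mean square error, coefficient of determination
#' \code{r2 = 1 - SS_res / SS_tot}, and the F statistic of the fitted model
#' against the constant-mean model with conventional degrees of freedom
#' (\code{n_params - 1} and \code{n - n_params}).
#'
#' @param obs,pred Equal-length observation and prediction vectors.
#' @param n_params Number of fitted parameters (including the intercept /
#'   baseline), \code{n_params < length(obs)}.
#' @return List with \code{rmse}, \code{r2}, \code{f_stat}, \code{df1},
#'   \code{df2}, \code{f_p}.
#' @export
goodness_of_fit <- function(obs, pred, n_params) {
  if (length(obs) != length(pred)) stop("obs and pred must have equal length")
  n <- length(obs)
  if (n_params >= n) stop("n_params must be smaller than the number of points")
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  df1 <- n_params - 1L
  df2 <- n - n_params
  f <- if (df1 > 0) ((ss_tot - ss_res) / df1) / (ss_res / df2) else NA_real_
  list(rmse = sqrt(ss_res / n),
       r2 = 1 - ss_res / ss_tot,
       f_stat = f, df1 = df1, df2 = df2,
       f_p = if (is.na(f)) NA_real_ else stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Synthetic LGMD-like firing-rate trace
#'
#' Samples \code{A * theta_dot * exp(-alpha * theta) + baseline} of a
#' constant-velocity approach over a window of times relative to collision
#' and adds seeded relative Gaussian noise.  A stand-in for resampled
#' neuronal recordings; synthetic by construction.
#'
#' @param stim An \code{\link{approach_stimulus}}.
#' @param eta An \code{\link{eta_params}} (amplitude, alpha, delay, baseline).
#' @param noise_rel Relative noise level (SD as a fraction of the clean
#'   sample value).
#' @param seed Integer seed.
#' @param window Window of times relative to collision, \code{c(from, to)}
#'   with \code{from < to <= 0} (default covers the approach up to just
#'   before contact).
#' @return A \code{\link{firing_rate_trace}}.
#' @export
synth_firing_trace <- function(stim, eta, noise_rel = 0, seed = 1L,
                               window = c(-stim$collision_time_tc + stim$dt,
                                          -stim$dt)) {
  if (window[2] + max(eta$delay_delta, 0) >= 0)
    stop("window must end before the (delay-shifted) contact instant")
  t_rel <- seq(window[1], window[2], by = stim$dt)
  clean <- eta$amplitude_C *
    model_shape("eta", t_rel, stim$half_size_R, stim$speed_v,
                eta$alpha, eta$delay_delta) + eta$baseline
  rate <- clean
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    rate <- clean * (1 + noise_rel * stats::rnorm(length(clean)))
  }
  firing_rate_trace(t_rel, rate, stim$half_size_R, stim$speed_v)
}

#' Linearity of fitted peak times in the half-size-to-speed ratio
#'
#' Regresses the observed peak delay \code{-t_peak_obs} (time before
#' collision) of a set of fits on their stimulus ratio \code{x = l / |v|}.
#' For eta-like responses the slope identifies alpha and the intercept a
#' temporal delay.
#'
#' @param fits List of \code{"fit_result"} objects with attached
#'   \code{x_ratio} values, or a data frame with columns \code{x_ratio} and
#'   \code{t_peak_obs}.
#' @return A \code{\link{weighted_line_fit}} result (unit weights).
#' @export
peak_linearity_report <- function(fits) {
  if (is.data.frame(fits)) {
    x <- fits$x_ratio
    delay <- -fits$t_peak_obs
  } else {
    x <- vapply(fits, function(f) f$x_ratio, numeric(1))
    delay <- vapply(fits, function(f) -f$t_peak_obs, numeric(1))
  }
  if (length(unique(x)) < 3L) stop("need >= 3 distinct x_ratio values")
  weighted_line_fit(x, delay, rep(1, length(x)))
}
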